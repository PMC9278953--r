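test_that("PV model rests stably near -70 mV with zero input", {
  tr <- simulate_cell(pv, 1000)
  late <- tr$v_mV[tr$time_ms > 200]
  expect_lt(diff(range(late)), 1)
  expect_lt(abs(mean(late) + 70), 3)
})

test_that("PV model fires high-frequency non-adapting trains", {
  tr <- pulse_trace(pv, 21)
  sp <- detect_spikes(tr)
  sp <- sp[sp > 50]
  isi <- diff(sp)
  expect_gt(length(sp), 50)           # > 165 Hz over 300 ms
  expect_lt(isi[length(isi)] / isi[1], 1.3)
})

test_that("passive variant reproduces the RC charging curve", {
  cell <- pv_with(gna_S_cm2 = 0, gkv3_S_cm2 = 0, gkv7_S_cm2 = 0)
  i_step <- 0.05  # nA
  tr <- simulate_cell(cell, 100, i_inj = i_step)
  p <- cell$params
  g_uS <- p$gl_S_cm2 * p$area_cm2 * 1e6
  c_nF <- p$cm_uF_cm2 * p$area_cm2 * 1e3
  tau <- c_nF / g_uS
  v_pred <- p$el + (i_step / g_uS) * (1 - exp(-tr$time_ms / tau))
  expect_lt(max(abs(tr$v_mV - v_pred)) / (i_step / g_uS), 1e-3)
})

test_that("integration is dt-convergent", {
  # subthreshold trajectory: halving dt changes the trace by < 0.5 mV RMS
  ev <- data.frame(onset = c(20, 60, 120), gmax = c(1, 0.8, 0.9))
  tr1 <- simulate_cell(pv, 200, dt = 0.025, exc_events = ev)
  tr2 <- simulate_cell(pv, 200, dt = 0.0125, exc_events = ev)
  v2 <- tr2$v_mV[seq(1, nrow(tr2), by = 2)]
  expect_lt(sqrt(mean((tr1$v_mV - v2)^2)), 0.5)
  # spiking protocol: spike count changes by <= 1 per 300 ms pulse
  cap <- cell_capacitance_pF(pv)
  i <- c(rep(0, 2000), rep(13 * cap * 1e-3, 12000))
  n1 <- length(detect_spikes(simulate_cell(pv, 350, dt = 0.025, i_inj = i)))
  i2 <- rep(i, each = 2)
  n2 <- length(detect_spikes(simulate_cell(pv, 350, dt = 0.0125, i_inj = i2)))
  expect_lte(abs(n1 - n2), 1)
})

test_that("zero-conductance compartment integrates injected current only", {
  cell <- pv_with(gna_S_cm2 = 0, gkv3_S_cm2 = 0, gkv7_S_cm2 = 0,
                  gl_S_cm2 = 0)
  tr <- simulate_cell(cell, 50, i_inj = 0, v0 = -55)
  expect_true(all(tr$v_mV == -55))
})

test_that("alpha conductance has the exact peak, onset, and integral", {
  expect_equal(alpha_conductance(5 + 0.5, onset_time = 5, gmax = 10,
                                 tau = 0.5), 10)
  expect_equal(alpha_conductance(4.999, onset_time = 5), 0)
  # closed-form integral over [0, 10 tau]:
  # gmax * tau * e * (1 - 11 e^-10)
  tau <- 0.7; gmax <- 3
  tt <- seq(0, 10 * tau, length.out = 200001)
  num <- sum(alpha_conductance(tt, 0, gmax, tau)) * (tt[2] - tt[1])
  expect_equal(num, gmax * tau * exp(1) * (1 - 11 * exp(-10)),
               tolerance = 1e-6)
})

test_that("a zero-conductance dynamic clamp leaves the trajectory unchanged", {
  ev <- data.frame(onset = c(30, 80), gmax = c(2, 2))
  base <- simulate_cell(pv, 150, exc_events = ev)
  clamped <- simulate_cell(attach_dynamic_clamp(pv, 0, -10), 150,
                           exc_events = ev)
  expect_identical(base$v_mV, clamped$v_mV)
})

test_that("compartment geometry conventions give the stated capacitance", {
  expect_equal(cell_capacitance_pF(pv), pi * 20 * 20 * 1e-8 * 1e6,
               tolerance = 1e-9)
  sq <- make_pv_cell(list(geometry = "square"))
  expect_equal(cell_capacitance_pF(sq), 4, tolerance = 1e-9)
})

test_that("simulation is deterministic and guards against blow-up", {
  a <- simulate_cell(pv, 300, i_inj = 0.2)
  b <- simulate_cell(pv, 300, i_inj = 0.2)
  expect_identical(a$v_mV, b$v_mV)
  expect_error(simulate_cell(pv, 10, dt = 0.5), "dt")
})

test_that("PC burster is silent/low-rate at rest, bursts, and rate is monotone in bias", {
  r0 <- length(detect_spikes(simulate_cell(pc, 2000))) / 2
  expect_lt(r0, 8)
  # suprathreshold step contains a multi-spike burst envelope
  tr <- simulate_cell(pc, 1500, i_inj = c(rep(0, 8000), rep(0.05, 52000)))
  sp <- detect_spikes(tr)
  sp <- sp[sp > 200]
  isi <- diff(sp)
  expect_gt(length(sp), 3)
  # at least one cluster: some ISI much shorter than the longest gap
  expect_gt(max(isi) / min(isi), 3)
  rates <- vapply(c(0.01, 0.03, 0.05), function(b)
    length(detect_spikes(simulate_cell(pc, 1500, i_inj = b))), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("unknown config entries are rejected", {
  expect_error(make_pv_cell(list(nonsense = 1)), "unknown")
  expect_error(make_pc_cell(list(gNa = 1)), "unknown")
})
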