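test_that("spike detection counts constructed events exactly", {
  dt <- 0.025
  flat <- rep(-70, 4000)
  expect_length(detect_spikes(flat, dt = dt), 0)
  # synthetic train of 7 template APs
  tmpl <- c(seq(-70, 30, length.out = 20), seq(30, -70, length.out = 20))
  v <- rep(-70, 8000)
  onsets <- round(seq(500, 7500, length.out = 7))
  for (o in onsets) v[o:(o + 39)] <- tmpl
  expect_length(detect_spikes(v, dt = dt), 7)
  # 2x finer resampling preserves the count
  v2 <- approx(seq_along(v), v, n = 2 * length(v) - 1)$y
  expect_length(detect_spikes(v2, dt = dt / 2), 7)
  # non-uniform sampling is rejected
  bad <- data.frame(time_ms = cumsum(runif(100)), v_mV = rep(-70, 100))
  expect_error(detect_spikes(bad), "non-uniform")
})

test_that("AP metrics recover the geometry of a constructed spike", {
  dt <- 0.025
  # triangular spike: linear rise -60 -> +40 over 0.5 ms, fall over 1 ms
  up <- seq(-60, 40, length.out = 21)     # 0.5 ms rise, 200 V/s
  dn <- seq(40, -60, length.out = 41)[-1] # 1 ms fall
  v <- c(rep(-60, 400), up, dn, rep(-60, 400))
  sp <- detect_spikes(v, dt = dt)
  m <- ap_metrics(v, sp[1], dvdt_criterion = 20, dt = dt)
  # threshold is the first sample of the ramp (dV/dt = 200 V/s throughout)
  expect_equal(m$threshold, -60, tolerance = 0.5)
  expect_equal(m$amplitude, 100, tolerance = 1)
  # half level at -10 mV: crossing at 0.35 ms up, 0.5 + 0.5 down -> 0.75 ms
  expect_equal(m$half_width, 0.75, tolerance = 0.03)
  expect_equal(m$max_dvdt, 100 / 0.5, tolerance = 1)
})

test_that("F-I curve starts at zero, is monotone, and matches its definition", {
  fi <- run_fi_curve(pv, amplitudes = c(0, 5, 9, 15, 21))
  expect_equal(fi$freq_Hz[1], 0)
  expect_true(all(diff(fi$freq_Hz) >= 0))
  expect_equal(fi$freq_Hz, fi$n_spikes / 0.3)
})

test_that("voltage-clamp family round-trips through the fitting stage", {
  vc <- run_vclamp_activation(gmax = 20, delta_shift = 0,
                              steps = seq(-90, 50, by = 20))
  # no current at the reversal potential
  vc_rev <- run_vclamp_activation(steps = c(-90))
  expect_lt(max(abs(vc_rev$peaks$i_peak_nA)), 1e-12)
  # chord conductance -> Boltzmann fit recovers the half-activation
  pk <- vc$peaks[vc$peaks$step_mV > -90, ]
  g <- chord_conductance(pk$i_peak_nA, pk$step_mV, -90)
  fit <- fit_boltzmann(pk$step_mV, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$v_half - (-5)), 0.5)
  # under a -10 mV shift the fitted half-activation follows
  vc10 <- run_vclamp_activation(gmax = 20, delta_shift = -10)
  pk10 <- vc10$peaks[vc10$peaks$step_mV > -90, ]
  g10 <- chord_conductance(pk10$i_peak_nA, pk10$step_mV, -90)
  fit10 <- fit_boltzmann(pk10$step_mV, g10)
  expect_lt(abs(fit10$v_half - (-15)), 0.5)
  # mono-exponential rise fit recovers the activation time constant
  tr <- vc$traces[vc$traces$step_mV == 10, ]
  seg <- tr[tr$time_ms <= 20, ]
  ft <- fit_monoexp_rise(seg$time_ms, seg$i_nA)
  expect_lt(abs(ft$tau - kv3_mtau(10)) / kv3_mtau(10), 0.05)
})

test_that("bombardment without synapses returns the intrinsic rate", {
  b <- run_bombardment(pv, 0, n_seeds = 1, n_exc = 0, n_inh = 0,
                       i_bias = 0.15)
  cap <- cell_capacitance_pF(pv)
  intrinsic <- length(detect_spikes(simulate_cell(pv, 1000, i_inj = 0.15)))
  expect_equal(b$rate_Hz, intrinsic)
})

test_that("bombardment is reproducible and shift-sensitive", {
  b1 <- run_bombardment(pv, c(0, -10), n_seeds = 2, seed = 5)
  b2 <- run_bombardment(pv, c(0, -10), n_seeds = 2, seed = 5)
  expect_identical(b1$rate_Hz, b2$rate_Hz)
  s <- attr(b1, "summary")
  expect_lt(s$mean_rate_Hz[s$delta_shift == -10],
            s$mean_rate_Hz[s$delta_shift == 0])
})

test_that("gEPSP trains evoke no spikes at zero conductance", {
  r <- run_gepsp_train(pv, g_epsp = 0, n_events = 5)
  expect_true(all(r$probability == 0))
})

test_that("subthreshold EPSP amplitude needs the Kv3 conductance to be shift-sensitive", {
  # passive variant (Kv3 removed): amplitude independent of delta_shift
  cell <- pv_with(gkv3_S_cm2 = 0, gna_S_cm2 = 0)
  ep <- run_subthreshold_epsp(cell, g_epsp = 1, delta_shifts = c(0, -10))
  expect_equal(ep$epsp_mV[1], ep$epsp_mV[2], tolerance = 1e-6)
  # a suprathreshold event is reported as an error
  expect_error(run_subthreshold_epsp(pv, g_epsp = 10), "suprathreshold")
})
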