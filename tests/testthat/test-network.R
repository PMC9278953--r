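test_that("connectivity draws respect the edge probabilities", {
  spec0 <- network_spec(p_pc_pc = 0, p_pv_pc = 0, p_pv_pv_chem = 0,
                        p_pv_pv_gap = 0, p_pc_pv = 0)
  net0 <- build_network(spec0, 1)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$gaps), 0)

  spec1 <- network_spec(n_pc = 10, n_pv = 5, p_pc_pc = 1, p_pv_pc = 1,
                        p_pv_pv_chem = 1, p_pv_pv_gap = 1, p_pc_pv = 1)
  net1 <- build_network(spec1, 1)
  expect_equal(nrow(net1$edges), 10 * 9 + 10 * 5 + 5 * 10 + 5 * 4)
  expect_equal(nrow(net1$gaps), 5 * 4 / 2)
  expect_true(all(net1$edges$pre != net1$edges$post))

  # binomial statistics of the PV->PC projection over many seeds
  spec <- network_spec()
  fr <- vapply(1:100, function(s) {
    net <- build_network(spec, s)
    sum(net$edges$is_inh & net$edges$post <= 200) / (20 * 200)
  }, numeric(1))
  se <- sqrt(0.36 * 0.64 / (20 * 200)) / sqrt(100)
  expect_lt(abs(mean(fr) - 0.36), 3 * se)
})

test_that("a fully decoupled network reproduces isolated-cell rates", {
  spec <- network_spec(n_pc = 4, n_pv = 3, p_pc_pc = 0, p_pv_pc = 0,
                       p_pv_pv_chem = 0, p_pv_pv_gap = 0, p_pc_pv = 0)
  net <- build_network(spec, 1)
  run <- run_network(net, 0, seed = 5)
  # reconstruct the per-cell bias and initial-voltage draws
  set.seed(5)
  bias <- c(runif(4, spec$pc_bias_nA[1], spec$pc_bias_nA[2]),
            runif(3, spec$pv_bias_nA[1], spec$pv_bias_nA[2]))
  v0 <- runif(7, -75, -60)
  for (c_id in 1:7) {
    cell <- if (c_id <= 4) pc else pv
    tr <- simulate_cell(cell, 1000, i_inj = bias[c_id], v0 = v0[c_id])
    iso <- length(detect_spikes(tr, threshold = -10, refractory = 1.5))
    expect_equal(unname(run$rates[c_id]), iso, tolerance = 0.01)
  }
})

test_that("network runs are bit-reproducible per seed", {
  spec <- network_spec(n_pc = 20, n_pv = 4, duration = 300)
  net <- build_network(spec, 2)
  a <- run_network(net, -5, seed = 9)
  b <- run_network(net, -5, seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp_mV, b$lfp_mV)
})

test_that("gap junction current is antisymmetric and equalizes voltages", {
  # two PV cells coupled only by a gap junction, started apart, no drive
  res <- kv3net:::.simulate_network_cpp(
    make_pc_cell()$params,
    within(make_pv_cell()$params, kv3_mtau_parse <- 0L),
    1L, 2L,
    integer(0), integer(0), numeric(0), logical(0),
    1L, 2L, 5,
    c(0, 0, 0), c(-70, -75, -55), 0.025, 20000,
    2, 5, 0, -80, 20L, -10, 1.5, 40L, c(1L, 2L))
  v <- res$v_rec
  gap_start <- abs(v[1, 1] - v[1, 2])
  gap_end <- abs(v[nrow(v), 1] - v[nrow(v), 2])
  expect_lt(gap_end, gap_start / 5)
  # conservation: coupled pair drifts to a common potential between them
  expect_gt(v[nrow(v), 1], -75)
  expect_lt(v[nrow(v), 2], -55)
})

test_that("Welch spectrum localizes a pure sinusoid and scales with power", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x1 <- sin(2 * pi * 40 * t)
  sp1 <- welch_psd(x1, fs)
  expect_equal(sp1$freq[which.max(sp1$psd)], 40)
  # Parseval: total spectral power ~ variance of the signal
  df <- sp1$freq[2] - sp1$freq[1]
  expect_equal(sum(sp1$psd) * df, var(x1), tolerance = 0.05)
  # doubling amplitude quadruples band power
  sp2 <- welch_psd(2 * x1, fs)
  band <- sp1$freq >= 30 & sp1$freq <= 50
  expect_equal(mean(sp2$psd[band]) / mean(sp1$psd[band]), 4,
               tolerance = 1e-6)
})

test_that("compute_lfp validates duration and returns a nonnegative spectrum", {
  expect_error(compute_lfp(rnorm(100), fs = 1000), "2 periods")
  lf <- compute_lfp(sin(2 * pi * 40 * seq(0, 1, by = 1e-3)), fs = 1000)
  expect_true(all(lf$spectrum$psd_mV2_Hz >= 0))
  expect_equal(lf$spectrum$freq_Hz[which.max(lf$spectrum$psd_mV2_Hz)], 40)
})

test_that("synchrony metric is 1 for duplicated trains and ~0 for independent ones", {
  st <- sort(runif(40, 0, 1000))
  spikes <- data.frame(cell_id = rep(1:2, each = 40),
                       time_ms = rep(st, 2))
  expect_equal(synchrony_metrics(spikes, 1000)$mean_correlation, 1,
               tolerance = 1e-12)
  trains <- generate_poisson_trains(20, 1000, 40, seed = 6)
  spikes_i <- data.frame(
    cell_id = rep(seq_along(trains), lengths(trains)),
    time_ms = unlist(trains))
  m <- synchrony_metrics(spikes_i, 1000)
  expect_lt(abs(m$mean_correlation), 0.05)
})

test_that("exponential-trend machinery flags a flat gamma-shift relation", {
  set.seed(3)
  flat <- fit_exponential_trend(0:10, rep(1, 11) + rnorm(11, 0, 1e-3))
  expect_true(is.na(flat$r_squared) || flat$r_squared < 0.5 ||
              abs(flat$a * flat$b) < 1e-4)
})
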