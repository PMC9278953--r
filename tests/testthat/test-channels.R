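test_that("Kv3 steady-state activation has the calibrated half-activation voltages", {
  expect_equal(kv3_minf(-5), 0.5, tolerance = 1e-12)
  expect_equal(kv3_minf(-15, delta_shift = -10), 0.5, tolerance = 1e-12)
  expect_lt(kv3_minf(-200), 1e-6)
  # strictly increasing over a wide grid, for every shift
  for (ds in c(-30, -10, 0, 10, 30)) {
    v <- seq(-120, 60, by = 1)
    expect_true(all(diff(kv3_minf(v, ds)) > 0))
  }
})

test_that("Kv3 inactivation is a decreasing sigmoid centred at -30 mV", {
  expect_equal(kv3_hinf(-30), 0.5, tolerance = 1e-12)
  expect_lt(kv3_hinf(200), 1e-6)
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(kv3_hinf(v)) < 0))
  # the shift translates the curve rigidly
  for (d in c(-10, -5, 5)) {
    expect_equal(kv3_hinf(-30 + d, delta_shift = d), 0.5, tolerance = 1e-12)
  }
})

test_that("Kv3 time constant is bell-shaped with a 0.5 ms floor", {
  expect_equal(kv3_mtau(-25), 4.5, tolerance = 1e-12)
  expect_equal(kv3_mtau(1e4), 0.5, tolerance = 1e-9)
  expect_equal(kv3_mtau(-1e4), 0.5, tolerance = 1e-9)
  # peak follows the shift
  v <- seq(-120, 60, by = 0.5)
  for (ds in c(-10, 0, 10)) {
    expect_equal(v[which.max(kv3_mtau(v, ds))], -25 + ds)
  }
  # kin_scale multiplies the Gaussian term only under the default parse
  expect_equal(kv3_mtau(-25, kin_scale = 2), 0.5 + 2 * 4, tolerance = 1e-12)
  # ... and the whole expression under the alternative parse
  expect_equal(kv3_mtau(-25, kin_scale = 2, parse = "whole"), 9,
               tolerance = 1e-12)
  expect_error(kv3_mtau(-25, kin_scale = 0), "kin_scale")
})

test_that("all gating curves are shift-covariant: f(v, d) == f(v - d, 0)", {
  v <- seq(-100, 40, by = 2.5)
  for (d in c(-30, -10, 7.5, 30)) {
    expect_equal(kv3_minf(v, d), kv3_minf(v - d, 0))
    expect_equal(kv3_hinf(v, d), kv3_hinf(v - d, 0))
    expect_equal(kv3_mtau(v, d), kv3_mtau(v - d, 0))
    expect_equal(kv7_minf(v, d), kv7_minf(v - d, 0))
  }
})

test_that("Kv7 activation is centred at -27 mV and saturates", {
  expect_equal(kv7_minf(-27), 0.5, tolerance = 1e-12)
  expect_equal(kv7_minf(-37, delta_shift = -10), 0.5, tolerance = 1e-12)
  expect_gt(kv7_minf(100), 1 - 1e-6)
  v <- seq(-120, 60, by = 1)
  expect_true(all(diff(kv7_minf(v)) > 0))
  expect_true(all(kv7_mtau(v) > 0))
})

test_that("HH sodium rates handle the removable singularity and scale kinetics", {
  # singular point of alpha_m at v = -40 (shift 0)
  r <- nav_hh_rates(-40)
  expect_true(all(is.finite(unlist(r))))
  # limit check against values just next to the singularity
  r_eps <- nav_hh_rates(-40 + 1e-7)
  expect_equal(r$mtau, r_eps$mtau, tolerance = 1e-5)
  # textbook steady states at -65 (resting): m ~ 0.053, h ~ 0.596
  r65 <- nav_hh_rates(-65)
  am <- 0.1 * (-25) / (1 - exp(2.5)); bm <- 4
  ah <- 0.07; bh <- 1 / (1 + exp(3))
  expect_equal(r65$minf, am / (am + bm), tolerance = 1e-10)
  expect_equal(r65$hinf, ah / (ah + bh), tolerance = 1e-10)
  # kin_scale halves both taus
  r_half <- nav_hh_rates(seq(-80, 0, 10), kin_scale = 0.5)
  r_full <- nav_hh_rates(seq(-80, 0, 10), kin_scale = 1)
  expect_equal(r_half$mtau, r_full$mtau / 2)
  expect_equal(r_half$htau, r_full$htau / 2)
  # monotone steady states
  v <- seq(-100, 20, by = 1)
  expect_true(all(diff(nav_hh_rates(v)$minf) > 0))
  expect_true(all(diff(nav_hh_rates(v)$hinf) < 0))
})

test_that("gate_step matches the closed-form exponential relaxation", {
  p <- gate_params("kv3")
  # fixed point: starting at steady state stays there
  v <- -40
  st <- list(m = kv3_minf(v), h = kv3_hinf(v))
  st2 <- gate_step(st, v, dt = 0.5, p)
  expect_equal(st2$m, st$m, tolerance = 1e-12)
  expect_equal(st2$h, st$h, tolerance = 1e-12)
  # semigroup: k substeps == one big step (constant v)
  st <- list(m = 0.1, h = 0.9)
  one <- gate_step(st, v, dt = 1, p)
  many <- st
  for (k in 1:10) many <- gate_step(many, v, dt = 0.1, p)
  expect_equal(many$m, one$m, tolerance = 1e-12)
  expect_equal(many$h, one$h, tolerance = 1e-12)
  # closed-form oracle after arbitrary time
  tau <- kv3_mtau(v)
  t_tot <- 5 * tau
  st5 <- list(m = 0, h = kv3_hinf(v))
  for (k in 1:50) st5 <- gate_step(st5, v, dt = t_tot / 50, p)
  expect_equal(st5$m, kv3_minf(v) * (1 - exp(-5)), tolerance = 1e-9)
  expect_error(gate_step(st, v, dt = 0, p), "dt")
})

test_that("channel_current follows Ohm's law with the stated conventions", {
  spec <- channel_spec("kv3", gbar = 20, e_rev = -90, gbar_mode = "absolute",
                       gate_exponents = c(1, 1))
  expect_equal(channel_current(spec, list(m = 1, h = 1), -80), 0.2)
  expect_equal(channel_current(spec, list(m = 1, h = 1), -90), 0)
  expect_equal(channel_current(spec, list(m = 0, h = 1), 0), 0)
  # positive = outward above reversal
  expect_gt(channel_current(spec, list(m = 0.5, h = 1), 0), 0)
})

test_that("compiled gating matches the R reference implementation", {
  v <- seq(-110, 50, by = 0.5)
  for (ds in c(-10, 0, 6)) {
    cc <- kv3net:::.kv3_gating_cpp(v, ds, 1.3, 0L)
    expect_equal(cc$minf, kv3_minf(v, ds), tolerance = 1e-14)
    expect_equal(cc$hinf, kv3_hinf(v, ds), tolerance = 1e-14)
    expect_equal(cc$mtau, kv3_mtau(v, ds, 1.3), tolerance = 1e-14)
  }
  rc <- kv3net:::.nav_hh_rates_cpp(v, 5, 0.15)
  rr <- nav_hh_rates(v, 5, 0.15)
  expect_equal(rc$minf, rr$minf, tolerance = 1e-12)
  expect_equal(rc$htau, rr$htau, tolerance = 1e-12)
})
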