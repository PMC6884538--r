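test_that("Super-Lorentzian lineshape matches the independent quadrature oracle", {
  offsets <- as.numeric(names(SL_ORACLE)) * 1000
  g <- superlorentzian_lineshape(offsets, 7.3e-6)
  expect_equal(g, unname(SL_ORACLE), tolerance = 1e-10)
})

test_that("lineshape decays monotonically with offset and is positive", {
  offsets <- c(1, 2, 5, 10, 20, 50, 100) * 1000
  g <- superlorentzian_lineshape(offsets, 7.3e-6)
  expect_true(all(g > 0))
  expect_true(all(diff(g) < 0))
})

test_that("lineshape depends on offset and T2 through their product, amplitude through T2", {
  expect_equal(superlorentzian_lineshape(10e3, 10e-6),
               2 * superlorentzian_lineshape(20e3, 5e-6),
               tolerance = 1e-10)
  expect_equal(superlorentzian_lineshape(10e3, 10e-6), SL_ORACLE_10K_10US,
               tolerance = 1e-10)
  expect_equal(superlorentzian_lineshape(20e3, 5e-6), SL_ORACLE_20K_5US,
               tolerance = 1e-10)
})

test_that("lineshape rejects near-resonance offsets", {
  expect_error(superlorentzian_lineshape(100, 7.3e-6), "cutoff")
  expect_error(superlorentzian_lineshape(-5000, 7.3e-6), "cutoff")
})

test_that("CW power equivalent matches the envelope-integral oracle and its scalings", {
  w1 <- cw_power_equivalent(1000, 8, 40.6)
  expect_equal(w1, CWPE_ORACLE_1000_8_406, tolerance = 1e-8)
  # linear in flip angle
  expect_equal(cw_power_equivalent(2000, 8, 40.6), 2 * w1, tolerance = 1e-12)
  expect_equal(cw_power_equivalent(0, 8, 40.6), 0)
  # sqrt duty-cycle scaling: halving the preparation period doubles the duty
  expect_equal(cw_power_equivalent(1000, 8, 20.3), sqrt(2) * w1,
               tolerance = 1e-10)
  expect_error(cw_power_equivalent(1000, 50, 40.6), "duty")
})

test_that("forward signal reproduces the independent steady-state evaluation", {
  p <- tissue_params(mmf = 0.17, t2_mm_us = 7.3, t2_w_ms = 2,
                     t1_obs_ms = 800, exch_rate = 30)
  sig <- forward_signal(p, default_mt_protocol())
  expect_equal(unname(sig$values), RAMANI_ORACLE_GRID, tolerance = 1e-8)
})

test_that("forward signal is bounded and monotone over random parameter draws", {
  protocol <- default_mt_protocol()
  set.seed(42)
  for (i in 1:100) {
    sig <- forward_signal(random_tissue_params(), protocol)$values
    expect_true(all(sig > 0 & sig <= 1))
    # non-increasing in power at fixed offset
    expect_true(all(apply(sig, 2, function(col) all(diff(col) <= 1e-12))))
    # non-decreasing in offset at fixed power
    expect_true(all(apply(sig, 1, function(row) all(diff(row) >= -1e-12))))
  }
})

test_that("signal at 1000 deg / 5 kHz decreases strictly with macromolecular fraction", {
  protocol <- mt_protocol(powers_deg = 1000, offsets_khz = 5)
  mmfs <- seq(0.05, 0.40, by = 0.05)
  s <- vapply(mmfs, function(f) {
    forward_signal(tissue_params(f, 7.3, 2, 800, 30), protocol)$values[1, 1]
  }, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("without a macromolecular pool the far-off-resonance signal is full", {
  p <- tissue_params(mmf = 0, t2_mm_us = 7.3, t2_w_ms = 2,
                     t1_obs_ms = 800, exch_rate = 30)
  protocol <- mt_protocol(powers_deg = c(500, 1500), offsets_khz = 50)
  s <- forward_signal(p, protocol)$values
  expect_true(all(abs(s - 1) < 0.02))
})

test_that("strong low-offset saturation attenuates more than weak far-offset saturation", {
  p <- tissue_params(mmf = 0.213, t2_mm_us = 7.3, t2_w_ms = 2,
                     t1_obs_ms = 735, exch_rate = 30)
  s <- forward_signal(p, default_mt_protocol())$values
  expect_lt(s["1500", "2"], s["500", "50"])
})

test_that("Rician noise has the zero-noise limit and is seed-reproducible", {
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  sig <- forward_signal(p, default_mt_protocol())
  expect_identical(add_rician_noise(sig, Inf, 1), sig)
  n1 <- add_rician_noise(sig, 50, seed = 99)
  n2 <- add_rician_noise(sig, 50, seed = 99)
  expect_identical(n1$values, n2$values)
  expect_true(n1$noisy)
  expect_false(identical(n1$values, sig$values))
})

test_that("Rician sample mean matches the closed-form Laguerre expression", {
  v <- 0.5; snr <- 50; sigma <- 1 / snr
  set.seed(7)
  draws <- utemt:::rician_transform(rep(v, 1e4), sigma)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - rician_mean_analytic(v, sigma)), 3 * se)
})

test_that("add_rician_noise does not alter the RNG state of the session", {
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  sig <- forward_signal(p, default_mt_protocol())
  set.seed(123)
  before <- .Random.seed
  invisible(add_rician_noise(sig, 50, seed = 5))
  expect_identical(.Random.seed, before)
})
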