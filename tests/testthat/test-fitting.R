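noiseless_sat <- function(mmf, t2mm, t1, exch = 30, t2w = 2) {
  forward_signal(tissue_params(mmf, t2mm, t2w, t1, exch),
                 default_mt_protocol())
}

test_that("variable-TR T1 fit recovers noiseless generating values exactly", {
  trs <- c(20, 80, 150)
  for (t1_true in c(823, 735, 1400)) {
    sig <- 1.7 * (1 - exp(-trs / t1_true)) + 0.05
    fit <- fit_t1_vtr(sig, trs)
    expect_true(fit$converged)
    expect_lt(abs(fit$t1_ms - t1_true) / t1_true, 1e-3)
    expect_equal(fit$amplitude, 1.7, tolerance = 1e-4)
    expect_equal(fit$constant, 0.05, tolerance = 1e-4)
  }
})

test_that("T1 fit flags degenerate and under-determined inputs", {
  expect_false(fit_t1_vtr(rep(0.3, 3), c(20, 80, 150))$converged)
  expect_error(fit_t1_vtr(c(1, 2), c(20, 80)), "at least 3")
  expect_error(fit_t1_vtr(c(1, 2, 3), c(20, 150, 80)), "increasing")
})

test_that("AFI relation recovers the actual flip angle from simulated steady states", {
  for (fa in c(45, 30)) {
    s <- afi_signals_oracle(800, fa, 20, 100)
    expect_lt(abs(afi_actual_fa(s[1], s[2], 20, 100) - fa), 0.5)
  }
  # zero-flip limit: equal signals
  expect_equal(afi_actual_fa(0.2, 0.2, 20, 100), 0)
  expect_error(afi_actual_fa(1, 0.1, 20, 100), "non-physical")
})

test_that("two-pool fit recovers tendon-range generating parameters from noiseless grids", {
  cases <- list(c(mmf = 0.213, t2mm = 7.3, t1 = 735),
                c(mmf = 0.141, t2mm = 7.3, t1 = 789),
                c(mmf = 0.170, t2mm = 7.3, t1 = 823))
  for (cs in cases) {
    fit <- fit_two_pool(noiseless_sat(cs["mmf"], cs["t2mm"], cs["t1"]),
                        t1_obs_ms = cs["t1"])
    expect_true(fit$converged)
    expect_lt(abs(fit$params$mmf - cs["mmf"]) / cs["mmf"], 0.01)
    expect_lt(abs(fit$params$t2_mm_us - cs["t2mm"]) / cs["t2mm"], 0.01)
  }
})

test_that("two-pool fit recovers 25 random in-bounds parameter sets within 1 percent", {
  set.seed(2024)
  protocol <- default_mt_protocol()
  for (i in 1:25) {
    p <- random_tissue_params()
    fit <- fit_two_pool(forward_signal(p, protocol), t1_obs_ms = p$t1_obs_ms)
    expect_lt(abs(fit$params$mmf - p$mmf) / p$mmf, 0.01)
    expect_lt(abs(fit$params$t2_mm_us - p$t2_mm_us) / p$t2_mm_us, 0.01)
    expect_lt(abs(fit$params$exch_rate - p$exch_rate) / p$exch_rate, 0.01)
  }
})

test_that("noisy grids at SNR 100 give sub-point median MMF error over replicates", {
  truth <- tissue_params(0.17, 7.3, 2, 800, 30)
  sig <- forward_signal(truth, default_mt_protocol())
  errs <- vapply(1:100, function(s) {
    noisy <- add_rician_noise(sig, snr = 100, seed = 1000 + s)
    fit <- fit_two_pool(noisy, t1_obs_ms = 800)
    abs(fit$params$mmf - truth$mmf)
  }, numeric(1))
  expect_lt(stats::median(errs) * 100, 1)   # percentage points
})

test_that("unsaturated (all-ones-like) data drives MMF to the lower bound and is flagged", {
  protocol <- default_mt_protocol()
  vals <- matrix(1, 3, 5)
  sat <- saturation_data(vals, protocol)
  fit <- fit_two_pool(sat, t1_obs_ms = 800)
  expect_lt(fit$params$mmf, 0.011)
  expect_true("mmf" %in% fit$at_bound)
})

test_that("two-pool fit errors when under-determined", {
  protocol <- mt_protocol(powers_deg = 1000, offsets_khz = c(2, 5, 10))
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  sat <- forward_signal(p, protocol)
  expect_error(fit_two_pool(sat, t1_obs_ms = 800), "under-determined")
})

test_that("fits are deterministic and the returned residual beats every start", {
  truth <- tissue_params(0.22, 8.5, 3, 900, 40)
  noisy <- add_rician_noise(forward_signal(truth, default_mt_protocol()),
                            snr = 60, seed = 3)
  f1 <- fit_two_pool(noisy, t1_obs_ms = 900)
  f2 <- fit_two_pool(noisy, t1_obs_ms = 900)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$residual_norm, f2$residual_norm)
  # residual at each deterministic initial point
  y <- as.vector(noisy$values)
  starts <- list(c(0.08, 5), c(0.17, 7.5), c(0.30, 12))
  for (st in starts) {
    model <- utemt:::.two_pool_grid(st[1], st[2], 2, 900, 30,
                                    default_mt_protocol())
    ssr0 <- sum((max(y) * as.vector(model) - y)^2)
    expect_lte(f1$residual_norm, ssr0 + 1e-12)
  }
})

test_that("voxelwise mapping recovers homogeneous regions and flags empty masks", {
  protocol <- default_mt_protocol()
  dims <- c(4, 4, 1)
  young <- tissue_params(0.213, 7.3, 2, 735, 30)
  stack <- array(0, c(dims, protocol$n_conditions))
  sig <- as.vector(forward_signal(young, protocol)$values)
  for (k in seq_along(sig)) stack[, , , k] <- sig[k]
  mask <- array(TRUE, dims)
  pm <- fit_voxelwise(stack, mask, protocol, t1_map = 735)
  expect_s3_class(pm, "parameter_map")
  expect_equal(stats::median(pm$mmf_map, na.rm = TRUE), 0.213,
               tolerance = 0.01)
  expect_error(fit_voxelwise(stack, array(FALSE, dims), protocol, 735),
               "empty mask")
})

test_that("pre-smoothing reduces voxelwise MMF dispersion under noise", {
  protocol <- default_mt_protocol()
  dims <- c(8, 8, 1)
  truth <- tissue_params(0.17, 7.3, 2, 800, 30)
  sig <- as.vector(forward_signal(truth, protocol)$values)
  clean <- array(0, c(dims, protocol$n_conditions))
  for (k in seq_along(sig)) clean[, , , k] <- sig[k]
  interior <- array(FALSE, dims); interior[3:6, 3:6, 1] <- TRUE
  sds <- vapply(1:3, function(s) {
    set.seed(500 + s)
    arr <- utemt:::rician_transform(clean, sigma = 1 / 50)
    sm <- arr
    for (k in seq_len(dim(arr)[4])) {
      sm[, , , k] <- gaussian_smooth_inplane(arr[, , , k])
    }
    raw_map <- fit_voxelwise(arr, interior, protocol, 800)
    sm_map <- fit_voxelwise(sm, interior, protocol, 800)
    c(raw = sd(raw_map$mmf_map[interior]), smooth = sd(sm_map$mmf_map[interior]))
  }, numeric(2))
  expect_true(all(sds["smooth", ] < sds["raw", ]))
})
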