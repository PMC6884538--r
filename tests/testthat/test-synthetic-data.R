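test_that("zero-SD distributions give every subject the cohort mean", {
  ref <- tendon_reference_table()
  ref[c("t1_sd", "mmf_pct_sd", "t2mm_sd")] <- 0
  spec <- cohort_spec(distributions = ref, exch_sd = 0, t2w_sd = 0, seed = 3)
  coh <- sample_cohort(spec)
  for (i in seq_len(nrow(ref))) {
    sub <- coh[coh$cohort == ref$cohort[i] & coh$tendon == ref$tendon[i], ]
    expect_true(all(sub$mmf_frac == ref$mmf_pct_mean[i] / 100))
    expect_true(all(sub$t1_ms == ref$t1_mean[i]))
  }
  expect_equal(nrow(coh), 2 * (26 + 22))
})

test_that("cohort sampling is seed-reproducible and respects cohort sizes", {
  spec <- cohort_spec(seed = 17)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)
  c3 <- sample_cohort(spec, seed = 18)
  expect_false(identical(c1, c3))
  expect_equal(sum(c1$cohort == "young"), 2 * 26)
  expect_equal(sum(c1$cohort == "elderly"), 2 * 22)
})

test_that("large-sample means converge to the generating distributions", {
  spec <- cohort_spec(n_young = 1e4, n_elderly = 1, seed = 5)
  coh <- sample_cohort(spec)
  ptt <- 100 * coh$mmf_frac[coh$cohort == "young" & coh$tendon == "PTT"]
  se <- sd(ptt) / sqrt(length(ptt))
  expect_lt(abs(mean(ptt) - 21.3), 3 * se)
  # within-subject ATT-PTT correlation near the spec value
  att <- 100 * coh$mmf_frac[coh$cohort == "young" & coh$tendon == "ATT"]
  expect_equal(cor(att, ptt), 0.5, tolerance = 0.05)
})

test_that("subject phantoms have disjoint, adequately sized tendon masks", {
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  ds <- generate_subject_dataset(p, p, default_mt_protocol(), snr = Inf)
  expect_gte(sum(ds$att_mask$mask), 20)
  expect_gte(sum(ds$ptt_mask$mask), 20)
  expect_false(any(ds$att_mask$mask & ds$ptt_mask$mask))
  expect_equal(dim(ds$mt_stack)[4], 15)
})

test_that("noiseless phantom data close the loop through the fit pipeline", {
  young <- tissue_params(0.213, 7.3, 2, 735, 30)
  old <- tissue_params(0.141, 7.3, 2, 789, 30)
  ds <- generate_subject_dataset(old, young, default_mt_protocol(),
                                 snr = Inf, dims = c(64, 64, 1))
  res <- fit_subject_dataset(ds, n_readers = 1, jitter_vox = 0, seed = 1,
                             smooth = FALSE)
  att <- res[res$tendon == "ATT", ]
  ptt <- res[res$tendon == "PTT", ]
  expect_equal(att$mmf_frac, 0.141, tolerance = 1e-4)
  expect_equal(ptt$mmf_frac, 0.213, tolerance = 1e-4)
  expect_equal(att$t1_ms, 789, tolerance = 1e-3)
  expect_equal(ptt$t1_ms, 735, tolerance = 1e-3)
  expect_equal(att$fa_actual_deg, 45, tolerance = 0.5)
})

test_that("reader simulation reproduces truth at zero jitter and varies otherwise", {
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  ds <- generate_subject_dataset(p, p, default_mt_protocol(), snr = Inf,
                                 dims = c(64, 64, 2))
  readers0 <- simulate_readers(ds$att_mask, 3, jitter_vox = 0, seed = 9)
  for (r in readers0) expect_identical(r$mask, ds$att_mask$mask)

  readers1 <- simulate_readers(ds$att_mask, 3, jitter_vox = 1, seed = 9)
  same <- vapply(readers1, function(r) identical(r$mask, ds$att_mask$mask),
                 logical(1))
  expect_false(all(same))
  # reproducible per seed
  readers1b <- simulate_readers(ds$att_mask, 3, jitter_vox = 1, seed = 9)
  for (k in 1:3) expect_identical(readers1[[k]]$mask, readers1b[[k]]$mask)
})

test_that("identical reader masks propagate to a downstream ICC of exactly 1", {
  set.seed(31)
  truth_vals <- rnorm(8, 0.17, 0.05)
  ratings <- simulate_reader_measurements(truth_vals, 3, noise_sd = 0, seed = 2)
  expect_equal(icc_absolute_agreement(ratings), 1)
})

test_that("reader measurement noise of half a point keeps ICC above 0.98", {
  # cohorts drawn from the reference distributions, readers with 0.5% MMF SD
  spec <- cohort_spec(seed = 41)
  coh <- sample_cohort(spec)
  mmf_pct <- 100 * coh$mmf_frac
  ratings <- simulate_reader_measurements(mmf_pct, 3, noise_sd = 0.5, seed = 8)
  expect_gt(icc_absolute_agreement(ratings), 0.98)
})

test_that("overlapping tendon regions are rejected at generation", {
  p <- tissue_params(0.17, 7.3, 2, 800, 30)
  expect_error(
    generate_subject_dataset(p, p, default_mt_protocol(), snr = Inf,
                             att_center = c(30, 32), ptt_center = c(34, 32)),
    "overlap")
})
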