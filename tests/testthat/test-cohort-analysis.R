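test_that("rank-sum exact p-values match brute-force enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    repeat {
      x <- round(rnorm(n1 + n2), 6)
      if (!anyDuplicated(x)) break
    }
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcoxon_exact_bruteforce(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum test is symmetric in the groups and null on identical groups", {
  a <- c(5.2, 3.1, 7.7, 4.4); b <- c(6.1, 2.2, 8.8, 5.0, 3.3)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcoxon_rank_sum(b, a)$p_value)
  same <- c(1, 2, 3, 4)
  expect_gt(wilcoxon_rank_sum(same, same)$p_value, 0.95)
  expect_error(wilcoxon_rank_sum(numeric(0), b), "at least 2")
})

test_that("rank-sum switches to the tie-corrected normal approximation", {
  a <- c(rep(1, 5), 2:10)   # ties, combined n > 20 with b
  b <- c(rep(1, 3), 5:12)
  res <- wilcoxon_rank_sum(a, b)
  expect_false(res$exact)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("ICC(2,1) is 1 for identical readers and matches the variance ratio", {
  x <- rnorm(10)
  expect_equal(icc_absolute_agreement(cbind(x, x, x)), 1)

  # readers = subject mean + noise of equal SD -> ICC ~ 0.5
  set.seed(21)
  n <- 1e4
  subj <- rnorm(n, 0, 1)
  ratings <- subj + matrix(rnorm(3 * n, 0, 1), n, 3)
  expect_equal(icc_absolute_agreement(ratings), 0.5, tolerance = 0.02)

  # with a reader main effect the agreement form matches the closed form
  # sigma_s^2 / (sigma_s^2 + sigma_r^2 + sigma_e^2); reader effects fixed
  # so their sample variance (the large-n limit of the reader component)
  # is known exactly
  se <- 0.7
  reader_fx <- c(-0.5, 0, 0.5)   # sample variance 0.25
  ratings2 <- subj + matrix(reader_fx, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, 0, se), n, 3)
  closed <- 1 / (1 + 0.25 + se^2)
  expect_equal(icc_absolute_agreement(ratings2), closed, tolerance = 0.02)
})

test_that("ICC handles degenerate and invalid inputs", {
  expect_warning(icc_absolute_agreement(matrix(1, 5, 3)), "degenerate")
  expect_error(icc_absolute_agreement(matrix(1:10, 5, 2)[, 1, drop = FALSE]),
               "2 readers")
  expect_error(icc_absolute_agreement(matrix(1:4, 2, 2)), "3 subjects")
})

test_that("percent difference reproduces the worked tendon examples", {
  expect_equal(round(percent_difference(21.3, 16.4), 1), -23.0)
  # the reported +3.6% was computed from unrounded cohort means; the
  # printed means give +3.67%
  expect_equal(percent_difference(735, 762), 3.6, tolerance = 0.15)
  expect_equal(percent_difference(5, 5), 0)
  expect_error(percent_difference(0, 1), "non-zero")
})

make_cohort_table <- function(n_readers = 3, reader_sd = 0,
                              n_young = 6, n_elderly = 5, seed = 1) {
  set.seed(seed)
  ref <- tendon_reference_table()
  rows <- list()
  for (co in c("young", "elderly")) {
    n <- if (co == "young") n_young else n_elderly
    for (i in seq_len(n)) {
      sid <- paste0(co, i)
      for (td in c("ATT", "PTT")) {
        r <- ref[ref$cohort == co & ref$tendon == td, ]
        for (rd in seq_len(n_readers)) {
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, cohort = co, tendon = td,
            reader_id = paste0("R", rd),
            t1_ms = r$t1_mean + rnorm(1, 0, reader_sd * 100),
            mmf_frac = r$mmf_pct_mean / 100 + rnorm(1, 0, reader_sd),
            t2mm_us = r$t2mm_mean + rnorm(1, 0, reader_sd))
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("a zero-variance cohort at the reference means reproduces them exactly", {
  tab <- make_cohort_table(reader_sd = 0)
  s <- summarize_cohort(tab)
  ref <- tendon_reference_table()
  for (i in seq_len(nrow(ref))) {
    row <- s$summary[s$summary$cohort == ref$cohort[i] &
                       s$summary$tendon == ref$tendon[i] &
                       s$summary$parameter == "MMF (%)", ]
    expect_equal(row$mean, ref$mmf_pct_mean[i], tolerance = 1e-12)
    expect_equal(row$sd, 0, tolerance = 1e-12)
  }
  ptt <- s$differences[s$differences$tendon == "PTT" &
                         s$differences$parameter == "MMF (%)", ]
  expect_equal(round(ptt$percent_difference, 1), -23.0)
})

test_that("cohort summary is invariant to row order and reports per-reader gaps", {
  tab <- make_cohort_table(reader_sd = 0.002, seed = 3)
  s1 <- summarize_cohort(tab)
  s2 <- summarize_cohort(tab[sample(nrow(tab)), ])
  expect_equal(s1$summary, s2$summary)
  expect_equal(s1$differences, s2$differences)
  expect_equal(s1$icc, s2$icc)
  expect_true(all(s1$icc$icc > 0.9))

  broken <- tab[-1, ]   # one reader row removed
  expect_error(summarize_cohort(broken), "missing reader rows")
})

test_that("a single-reader table reports ICC as not applicable", {
  tab <- make_cohort_table(n_readers = 1)
  s <- summarize_cohort(tab)
  expect_true(all(is.na(s$icc$icc)))
  expect_equal(unique(s$icc$n_readers), 1)
})
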