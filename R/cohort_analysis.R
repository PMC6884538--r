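#' Two-sided Wilcoxon rank-sum test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two independent groups of
#' possibly unequal size: the exact null distribution is used when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @return List with `statistic` (the Mann-Whitney U of `group_a`),
#'   `p_value` (two-sided) and `exact` (logical, which distribution was
#'   used).
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 values")
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  use_exact <- (length(group_a) + length(group_b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Intraclass correlation coefficient, absolute agreement, single rater
#'
#' ICC(2,1): two-way random-effects, absolute-agreement, single-rater form,
#' computed from the mean-squares decomposition of the subjects-by-readers
#' table,
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)},}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-reader and
#' \eqn{MS_E} the residual mean square over `n` subjects and `k` readers.
#' This is the conventional form for interchangeable independent readers.
#'
#' @param ratings Numeric matrix, subjects in rows and readers in columns
#'   (>= 3 subjects, >= 2 readers, no missing cells).
#' @return The ICC estimate, a scalar in (-1, 1].
#' @export
icc_absolute_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("at least 2 readers are required")
  if (n < 3) stop("at least 3 subjects are required")
  if (anyNA(ratings)) stop("missing cells are not supported")
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (den <= .Machine$double.eps) {
    warning("degenerate ratings: no between-subject variance; ICC undefined, returning 0")
    return(0)
  }
  (msr - mse) / den
}

#' Percent difference relative to the young-cohort mean
#'
#' `100 * (mean_elderly - mean_young) / mean_young`: negative values mean
#' the quantity is lower in the elderly cohort.
#'
#' @param mean_young,mean_elderly Cohort means (reference first).
#' @return Signed percent difference.
#' @examples
#' percent_difference(21.3, 16.4)   # -23.0: PTT macromolecular fraction
#' @export
percent_difference <- function(mean_young, mean_elderly) {
  if (!is.finite(mean_young) || mean_young == 0) {
    stop("reference (young) mean must be non-zero")
  }
  100 * (mean_elderly - mean_young) / mean_young
}

.cohort_cols <- c("subject_id", "cohort", "tendon", "reader_id",
                  "t1_ms", "mmf_frac", "t2mm_us")
.cohort_params <- c(t1_ms = "T1 (ms)", mmf_frac = "MMF (%)",
                    t2mm_us = "T2mm (us)")

#' Validate a cohort table
#'
#' A cohort table has one row per subject x tendon x reader with columns
#' `subject_id`, `cohort` (young/elderly), `tendon` (ATT/PTT), `reader_id`,
#' `t1_ms`, `mmf_frac` (fraction, not percent), `t2mm_us`.
#'
#' @param table A data.frame.
#' @return The table, invisibly; errors list any schema gaps.
#' @export
validate_cohort_table <- function(table) {
  missing <- setdiff(.cohort_cols, names(table))
  if (length(missing)) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(table$cohort %in% c("young", "elderly"))) {
    stop("cohort must be 'young' or 'elderly'")
  }
  if (!all(table$tendon %in% c("ATT", "PTT"))) {
    stop("tendon must be 'ATT' or 'PTT'")
  }
  key <- interaction(table$subject_id, table$tendon, table$reader_id)
  if (anyDuplicated(key)) stop("duplicate subject x tendon x reader rows")
  counts <- table(table$subject_id, table$tendon)
  readers <- unique(table$reader_id)
  if (any(counts > 0 & counts != length(readers))) {
    bad <- which(counts > 0 & counts != length(readers), arr.ind = TRUE)
    stop("missing reader rows for: ",
         paste(rownames(counts)[bad[, 1]], colnames(counts)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  invisible(table)
}

#' Cohort summary: group means, age differences and reader agreement
#'
#' Reproduces the study's summary layout from a per-reader cohort table:
#' reader measurements are first averaged within subject and tendon, then
#' cohort mean and sample SD are tabulated per tendon and parameter
#' (`summary` element); elderly-vs-young percent differences with two-sided
#' Wilcoxon rank-sum p-values per tendon and parameter (`differences`
#' element); and inter-reader ICC(2,1) per parameter, computed across all
#' subject-tendon units pooled over cohorts (`icc` element, `NA` when only
#' one reader is present).
#'
#' @param table A cohort table (see [validate_cohort_table()]).
#' @param alpha Significance threshold annotated in the difference table
#'   (no multiple-testing correction is applied).
#' @return List of data.frames `summary`, `differences`, `icc`, plus
#'   `per_subject` (the reader-averaged table).
#' @export
summarize_cohort <- function(table, alpha = 0.05) {
  validate_cohort_table(table)
  params <- names(.cohort_params)

  # reader-averaged per-subject values
  agg <- stats::aggregate(table[params],
                          by = table[c("subject_id", "cohort", "tendon")],
                          FUN = mean)
  agg <- agg[order(agg$cohort, agg$tendon, agg$subject_id), ]
  rownames(agg) <- NULL

  scale_of <- function(p, v) if (p == "mmf_frac") 100 * v else v

  summary_rows <- list()
  diff_rows <- list()
  for (tendon in c("ATT", "PTT")) {
    for (p in params) {
      y <- scale_of(p, agg[agg$cohort == "young" & agg$tendon == tendon, p])
      e <- scale_of(p, agg[agg$cohort == "elderly" & agg$tendon == tendon, p])
      if (!length(y) || !length(e)) stop("a cohort is empty for ", tendon)
      summary_rows[[paste("young", tendon, p)]] <-
        data.frame(cohort = "young", tendon = tendon,
                   parameter = .cohort_params[[p]],
                   mean = mean(y), sd = stats::sd(y), n = length(y))
      summary_rows[[paste("elderly", tendon, p)]] <-
        data.frame(cohort = "elderly", tendon = tendon,
                   parameter = .cohort_params[[p]],
                   mean = mean(e), sd = stats::sd(e), n = length(e))
      wt <- wilcoxon_rank_sum(y, e)
      diff_rows[[paste(tendon, p)]] <-
        data.frame(tendon = tendon, parameter = .cohort_params[[p]],
                   percent_difference = percent_difference(mean(y), mean(e)),
                   p_value = wt$p_value,
                   significant = wt$p_value < alpha)
    }
  }

  readers <- sort(unique(table$reader_id))
  icc_rows <- lapply(params, function(p) {
    icc <- NA_real_
    if (length(readers) >= 2) {
      wide <- stats::reshape(
        table[c("subject_id", "tendon", "reader_id", p)],
        idvar = c("subject_id", "tendon"), timevar = "reader_id",
        direction = "wide")
      ratings <- as.matrix(wide[, -(1:2), drop = FALSE])
      icc <- icc_absolute_agreement(ratings)
    }
    data.frame(parameter = .cohort_params[[p]], icc = icc,
               n_readers = length(readers))
  })

  list(summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
       differences = do.call(rbind, c(diff_rows, make.row.names = FALSE)),
       icc = do.call(rbind, icc_rows),
       per_subject = agg)
}
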