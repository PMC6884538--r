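#' Fit one subject's dataset through the full ROI pipeline
#'
#' Runs the per-subject analysis exactly as the cohort study does: Gaussian
#' in-plane pre-smoothing of every volume, simulated reader ROI placement,
#' AFI flip-angle check, ROI-mean variable-TR T1 fit, then the ROI-mean
#' two-pool MT fit using that reader's T1. ROI-level fitting operates on the
#' ROI-averaged signal per condition (not on averaged voxelwise fits),
#' normalized by the weakest-saturation condition with the amplitude left
#' free in the fit.
#'
#' @param dataset Output of [generate_subject_dataset()] (or an equivalent
#'   list read from disk).
#' @param n_readers,jitter_vox Reader simulation controls; reader masks are
#'   drawn per tendon with `seed + 1` (ATT) and `seed + 2` (PTT).
#' @param seed Integer seed for reader placement.
#' @param smooth Apply [gaussian_smooth_inplane()] before fitting.
#' @param erode_margin Voxels of in-plane erosion applied to each reader's
#'   mask before ROI averaging, so that boundary voxels carrying
#'   partial-volume signal from the surrounding tissue are excluded (the
#'   usual convention when measuring small structures). Set 0 to measure
#'   the full contour. If erosion would empty a mask the full mask is used.
#' @param ... Passed to [fit_two_pool()].
#' @return Data.frame with one row per tendon x reader: `tendon`,
#'   `reader_id`, `t1_ms`, `mmf_frac`, `t2mm_us`, `exch_rate`,
#'   `fa_actual_deg`, `mt_residual`.
#' @export
fit_subject_dataset <- function(dataset, n_readers = 3, jitter_vox = 1,
                                seed = 1L, smooth = TRUE, erode_margin = 1,
                                ...) {
  protocol <- dataset$protocol
  mt <- dataset$mt_stack
  vtr_stack <- dataset$vtr_stack
  afi_stack <- dataset$afi_stack
  if (smooth) {
    for (k in seq_len(dim(mt)[4])) {
      mt[, , , k] <- gaussian_smooth_inplane(mt[, , , k])
    }
    if (!is.null(vtr_stack)) {
      for (k in seq_len(dim(vtr_stack)[4])) {
        vtr_stack[, , , k] <- gaussian_smooth_inplane(vtr_stack[, , , k])
      }
    }
    if (!is.null(afi_stack)) {
      for (k in 1:2) {
        afi_stack[, , , k] <- gaussian_smooth_inplane(afi_stack[, , , k])
      }
    }
  }

  np <- length(protocol$powers_deg)
  no <- length(protocol$offsets_khz)
  rows <- list()
  for (tendon in c("ATT", "PTT")) {
    truth_mask <- if (tendon == "ATT") dataset$att_mask else dataset$ptt_mask
    readers <- simulate_readers(truth_mask, n_readers, jitter_vox,
                                seed = seed + if (tendon == "ATT") 1L else 2L)
    for (rd in readers) {
      meas_mask <- rd$mask
      if (erode_margin > 0) {
        for (e in seq_len(erode_margin)) {
          eroded <- .morph_mask(meas_mask, -1L)
          if (!any(eroded)) break
          meas_mask <- eroded
        }
      }
      roi_mean <- function(stack, k) mean(stack[, , , k][meas_mask])

      fa_actual <- NA_real_
      if (!is.null(afi_stack) && !is.null(dataset$vtr$afi_trs_ms)) {
        fa_actual <- afi_actual_fa(roi_mean(afi_stack, 1),
                                   roi_mean(afi_stack, 2),
                                   dataset$vtr$afi_trs_ms[1],
                                   dataset$vtr$afi_trs_ms[2])
      }

      t1_ms <- NA_real_
      if (!is.null(vtr_stack)) {
        sig <- vapply(seq_along(dataset$vtr$vtr_trs_ms),
                      function(k) roi_mean(vtr_stack, k), numeric(1))
        t1_fit <- fit_t1_vtr(sig, dataset$vtr$vtr_trs_ms)
        t1_ms <- t1_fit$t1_ms
      }

      mt_sig <- vapply(seq_len(protocol$n_conditions),
                       function(k) roi_mean(mt, k), numeric(1))
      ref <- max(mt_sig)
      vals <- matrix(pmin(mt_sig / ref, 1.05), np, no)
      sat <- saturation_data(vals, protocol, s0_reference = ref,
                             noisy = TRUE)
      fit <- fit_two_pool(sat, t1_obs_ms = t1_ms, ...)

      rows[[paste(tendon, rd$reader_id)]] <- data.frame(
        tendon = tendon, reader_id = rd$reader_id,
        t1_ms = t1_ms, mmf_frac = fit$params$mmf,
        t2mm_us = fit$params$t2_mm_us, exch_rate = fit$params$exch_rate,
        fa_actual_deg = fa_actual, mt_residual = fit$residual_norm)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' End-to-end synthetic cohort pipeline
#'
#' Samples a cohort from the spec, forward-simulates each subject's phantom
#' dataset, runs the full per-subject fitting pipeline with simulated
#' readers, and assembles the cohort table that feeds
#' [summarize_cohort()]. Deterministic for a fixed spec: per-subject seeds
#' are derived from `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @param dims Phantom dimensions per subject.
#' @param n_young,n_elderly Optional overrides of the spec's cohort sizes
#'   (e.g. to run a subset of subjects).
#' @param smooth Apply in-plane pre-smoothing (default on).
#' @param verbose Print one line per subject.
#' @return List with `table` (the cohort table), `truth` (the generating
#'   per-subject parameters) and `spec`.
#' @export
run_cohort_pipeline <- function(spec = cohort_spec(), dims = c(64, 64, 4),
                                n_young = spec$n_young,
                                n_elderly = spec$n_elderly,
                                smooth = TRUE, verbose = FALSE) {
  spec_run <- spec
  spec_run$n_young <- n_young
  spec_run$n_elderly <- n_elderly
  truth <- sample_cohort(spec_run)
  subjects <- unique(truth$subject_id)
  rows <- list()
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    sub <- truth[truth$subject_id == sid, ]
    par_of <- function(tendon) {
      r <- sub[sub$tendon == tendon, ]
      tissue_params(mmf = r$mmf_frac, t2_mm_us = r$t2mm_us,
                    t2_w_ms = r$t2w_ms, t1_obs_ms = r$t1_ms,
                    exch_rate = r$exch_rate, s0 = 1)
    }
    ds <- generate_subject_dataset(par_of("ATT"), par_of("PTT"),
                                   protocol = default_mt_protocol(),
                                   snr = spec_run$snr,
                                   seed = spec_run$seed + 1000L + i,
                                   dims = dims)
    res <- fit_subject_dataset(ds, n_readers = spec_run$n_readers,
                               jitter_vox = spec_run$reader_jitter_vox,
                               seed = spec_run$seed + 2000L + 10L * i,
                               smooth = smooth)
    res$subject_id <- sid
    res$cohort <- sub$cohort[1]
    rows[[sid]] <- res
    if (verbose) {
      message(sprintf("subject %s (%s): ATT MMF %.1f%%", sid, sub$cohort[1],
                      100 * mean(res$mmf_frac[res$tendon == "ATT"])))
    }
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab <- tab[c("subject_id", "cohort", "tendon", "reader_id",
               "t1_ms", "mmf_frac", "t2mm_us", "exch_rate",
               "fa_actual_deg", "mt_residual")]
  list(table = tab, truth = truth, spec = spec_run)
}

#' Parameter-level cohort replication
#'
#' The light-weight counterpart of [run_cohort_pipeline()]: repeatedly
#' samples cohorts from the spec's distributions (no imaging, no fitting)
#' and computes the elderly-vs-young percent difference of cohort means and
#' the two-sided Wilcoxon rank-sum p-value per tendon for the chosen
#' parameter. This isolates the sampling variability of the cohort
#' comparison itself.
#'
#' @param spec A [cohort_spec].
#' @param n_replicates Number of replicate cohorts.
#' @param parameter Which parameter column of [sample_cohort()] output to
#'   compare.
#' @return Data.frame with one row per replicate x tendon: `replicate`,
#'   `tendon`, `percent_difference`, `p_value`.
#' @export
replicate_cohort_comparison <- function(spec = cohort_spec(),
                                        n_replicates = 200,
                                        parameter = "mmf_frac") {
  rows <- vector("list", 2 * n_replicates)
  for (r in seq_len(n_replicates)) {
    coh <- sample_cohort(spec, seed = spec$seed + r - 1L)
    for (tendon in c("ATT", "PTT")) {
      y <- coh[coh$cohort == "young" & coh$tendon == tendon, parameter]
      e <- coh[coh$cohort == "elderly" & coh$tendon == tendon, parameter]
      wt <- wilcoxon_rank_sum(y, e)
      rows[[2 * (r - 1) + (tendon == "PTT") + 1]] <- data.frame(
        replicate = r, tendon = tendon,
        percent_difference = percent_difference(mean(y), mean(e)),
        p_value = wt$p_value)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
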