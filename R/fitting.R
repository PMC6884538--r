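#' Fit result container
#'
#' @param params Fitted [tissue_params] (fields not fitted carry the fixed
#'   values used).
#' @param residual_norm Sum of squared residuals at the solution.
#' @param n_iter Iterations used by the optimizer.
#' @param converged Logical convergence flag.
#' @param covariance_diag Named per-parameter variance estimates from the
#'   Jacobian at the solution (`NA` where unavailable).
#' @param extra Named list of method-specific fields (e.g. the fitted
#'   amplitude and constant of the T1 model).
#' @return An object of class `fit_result`.
#' @keywords internal
fit_result <- function(params, residual_norm, n_iter, converged,
                       covariance_diag = NULL, extra = list()) {
  stopifnot(residual_norm >= -1e-12)
  structure(c(list(params = params, residual_norm = max(residual_norm, 0),
                   n_iter = n_iter, converged = converged,
                   covariance_diag = covariance_diag), extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s, %d iterations, SSR %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$residual_norm))
  if (inherits(x$params, "tissue_params")) print(x$params)
  invisible(x)
}

.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
}

.cov_diag <- function(fit, names) {
  d <- rep(NA_real_, length(names))
  names(d) <- names
  dof <- length(fit$fvec) - length(fit$par)
  if (dof > 0) {
    s2 <- fit$deviance / dof
    h <- try(diag(solve(fit$hessian)) * s2, silent = TRUE)
    if (!inherits(h, "try-error") && all(is.finite(h))) d[] <- h
  }
  d
}

#' Variable-TR single-exponential T1 fit
#'
#' Fits the saturation-recovery model
#' \deqn{S(TR) = A\,(1 - e^{-TR/T_1}) + C}
#' to a series of magnitudes acquired at increasing repetition times, by
#' bounded Levenberg-Marquardt least squares. T1 is constrained to
#' \[100, 5000\] ms.
#'
#' @param signals Magnitudes, arbitrary units (>= 0), one per TR.
#' @param trs_ms Repetition times, ms; at least 3 distinct, strictly
#'   increasing values.
#' @param t1_init_ms Starting value for T1, ms.
#' @return A `fit_result`; `params$t1_obs_ms` holds the estimate and
#'   the fields `amplitude` and `constant` hold A and C. A degenerate
#'   (flat) series is returned with `converged = FALSE`.
#' @export
fit_t1_vtr <- function(signals, trs_ms, t1_init_ms = 500) {
  stopifnot(length(signals) == length(trs_ms))
  if (length(unique(trs_ms)) < 3) {
    stop("under-determined: at least 3 distinct TRs are required")
  }
  if (any(diff(trs_ms) <= 0)) stop("trs_ms must be strictly increasing")
  if (any(signals < 0)) stop("signals must be non-negative")

  smax <- max(signals)
  flat <- (smax - min(signals)) <= 1e-12 * max(smax, 1)
  resid_fn <- function(p) {
    p["A"] * (1 - exp(-trs_ms / p["T1"])) + p["C"] - signals
  }
  fit <- minpack.lm::nls.lm(
    par = c(A = if (smax > 0) smax else 1, T1 = t1_init_ms, C = 0),
    lower = c(A = 0, T1 = 100, C = -Inf),
    upper = c(A = Inf, T1 = 5000, C = Inf),
    fn = resid_fn, control = .lm_control())
  p <- fit$par
  identifiable <- !flat && p[["A"]] > 1e-8 * max(smax, 1)
  converged <- fit$info %in% 1:4 && identifiable &&
    p[["T1"]] > 100 + 1e-6 && p[["T1"]] < 5000 - 1e-6
  prm <- tissue_params(mmf = 0, t2_mm_us = 7.3,
                       t1_obs_ms = p[["T1"]],
                       s0 = max(p[["A"]], 1e-12))
  fit_result(prm, fit$deviance, fit$niter, converged,
             covariance_diag = .cov_diag(fit, c("A", "T1", "C")),
             extra = list(t1_ms = p[["T1"]], amplitude = p[["A"]],
                          constant = p[["C"]]))
}

#' Actual flip angle from a dual-TR AFI pair
#'
#' The standard AFI relation: with signal ratio `r = signal2/signal1` and TR
#' ratio `n = tr2/tr1`, the actual excitation angle is
#' \eqn{\arccos((r n - 1)/(n - r))}, used to replace the nominal flip angle
#' before T1 mapping under B1 inhomogeneity.
#'
#' @param signal1,signal2 Steady-state magnitudes at the short and long TR.
#' @param tr1_ms,tr2_ms The two repetition times, ms (`tr2_ms > tr1_ms`).
#' @return Actual flip angle in degrees.
#' @export
afi_actual_fa <- function(signal1, signal2, tr1_ms, tr2_ms) {
  stopifnot(tr2_ms > tr1_ms, tr1_ms > 0, signal1 > 0, signal2 > 0)
  r <- signal2 / signal1
  n <- tr2_ms / tr1_ms
  if (r >= 1) {
    if (r <= 1 + 1e-9) return(0)  # zero-flip limit
    stop("non-physical AFI ratio: signal2/signal1 = ", round(r, 4), " >= 1")
  }
  if (r <= 1 / n) {
    stop("non-physical AFI ratio: signal2/signal1 must exceed tr1/tr2")
  }
  acos((r * n - 1) / (n - r)) * 180 / pi
}

#' Two-pool MT parameter fit
#'
#' Levenberg-Marquardt least-squares fit of the two-pool steady-state model
#' ([forward_signal()]) to a measured saturation grid, with the observed T1
#' held fixed. Free parameters are the macromolecular fraction, the
#' macromolecular T2, the exchange rate, the water T2 (optionally fixed) and
#' the amplitude. The fit is started from three deterministic initial points
#' bracketing the published tendon range (MMF 0.08/0.17/0.30 paired with
#' T2mm 5/7.5/12 microseconds) and the lowest-residual solution is returned,
#' so identical inputs always give identical results.
#'
#' @param data A [saturation_data] object.
#' @param t1_obs_ms Observed T1 for this ROI/voxel, ms.
#' @param fit_t2w Fit the water-pool T2 (default) or hold it at `t2w_fixed_ms`.
#' @param t2w_fixed_ms Water T2 used when `fit_t2w = FALSE`, ms.
#' @param lower,upper Named bounds for `mmf` (fraction), `t2_mm_us`,
#'   `exch_rate` (1/s), `t2_w_ms` and `s0` (relative to the data maximum).
#' @return A `fit_result` whose `params` carry the fitted values;
#'   `at_bound` in the result names any parameter pinned at a bound.
#' @export
fit_two_pool <- function(data, t1_obs_ms,
                         fit_t2w = TRUE, t2w_fixed_ms = 2,
                         lower = c(mmf = 0.01, t2_mm_us = 1, exch_rate = 1,
                                   t2_w_ms = 0.1, s0 = 0.1),
                         upper = c(mmf = 0.9, t2_mm_us = 50, exch_rate = 100,
                                   t2_w_ms = 100, s0 = 10)) {
  stopifnot(inherits(data, "saturation_data"), t1_obs_ms > 0)
  protocol <- data$protocol
  y <- as.vector(data$values)
  free <- c("mmf", "t2_mm_us", "exch_rate", if (fit_t2w) "t2_w_ms", "s0")
  if (length(y) < length(free)) {
    stop("under-determined: ", length(y), " conditions for ",
         length(free), " free parameters")
  }
  smax <- max(y)
  lo <- lower[free]; hi <- upper[free]
  lo["s0"] <- lower[["s0"]] * smax; hi["s0"] <- upper[["s0"]] * smax

  resid_fn <- function(p) {
    model <- .two_pool_grid(
      mmf = p[["mmf"]], t2_mm_us = p[["t2_mm_us"]],
      t2_w_ms = if (fit_t2w) p[["t2_w_ms"]] else t2w_fixed_ms,
      t1_obs_ms = t1_obs_ms, exch_rate = p[["exch_rate"]],
      protocol = protocol)
    p[["s0"]] * as.vector(model) - y
  }

  starts <- list(c(mmf = 0.08, t2_mm_us = 5, t2_w_ms = 1.5),
                 c(mmf = 0.17, t2_mm_us = 7.5, t2_w_ms = 5),
                 c(mmf = 0.30, t2_mm_us = 12, t2_w_ms = 15))
  best <- NULL
  for (st in starts) {
    par0 <- c(st[c("mmf", "t2_mm_us")], exch_rate = 30,
              if (fit_t2w) st["t2_w_ms"], s0 = smax)[free]
    par0 <- pmin(pmax(par0, lo), hi)
    fit <- minpack.lm::nls.lm(par = par0, lower = lo, upper = hi,
                              fn = resid_fn, control = .lm_control())
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  p <- best$par
  at_bound <- names(p)[p <= lo + 1e-9 | p >= hi - 1e-9]
  prm <- tissue_params(
    mmf = p[["mmf"]], t2_mm_us = p[["t2_mm_us"]],
    t2_w_ms = if (fit_t2w) p[["t2_w_ms"]] else t2w_fixed_ms,
    t1_obs_ms = t1_obs_ms, exch_rate = p[["exch_rate"]], s0 = p[["s0"]])
  fit_result(prm, best$deviance, best$niter,
             converged = best$info %in% 1:4,
             covariance_diag = .cov_diag(best, names(p)),
             extra = list(at_bound = at_bound, fit_t2w = fit_t2w))
}

#' Voxelwise two-pool parameter mapping
#'
#' Applies [fit_two_pool()] independently to every in-mask voxel of a
#' registered MT-weighted volume stack, using that voxel's T1, and assembles
#' parameter maps with a per-voxel residual-norm quality map. Failed voxels
#' are flagged missing and the pipeline continues; if more than half the
#' voxels fail a warning is raised.
#'
#' @param volumes 4-D array `x * y * z * condition`; the condition axis
#'   enumerates the protocol grid in column-major (power fastest) order, as
#'   produced by stacking `as.vector(values)` per voxel.
#' @param mask Logical 3-D array of voxels to fit.
#' @param protocol An [mt_protocol].
#' @param t1_map 3-D array of observed T1 (ms) per voxel, or a scalar.
#' @param s0_map 3-D array (or scalar) of the unsaturated reference used to
#'   normalize each voxel's signals; defaults to each voxel's maximum.
#' @param ... Passed to [fit_two_pool()].
#' @return An object of class `parameter_map`: list of 3-D arrays
#'   `mmf_map`, `t2mm_map`, `exch_map`, `t1_map`, `quality_map` (NA outside
#'   the mask or where the fit failed) plus the `mask`.
#' @export
fit_voxelwise <- function(volumes, mask, protocol, t1_map, s0_map = NULL,
                          ...) {
  stopifnot(length(dim(volumes)) == 4)
  dims <- dim(volumes)[1:3]
  if (!all(dim(mask) == dims)) stop("mask shape does not match volumes")
  if (!any(mask)) stop("empty mask: no voxels to fit")
  if (dim(volumes)[4] != protocol$n_conditions) {
    stop("condition axis (", dim(volumes)[4], ") does not match the ",
         "protocol grid (", protocol$n_conditions, ")")
  }
  if (length(t1_map) == 1) t1_map <- array(t1_map, dims)
  empty <- array(NA_real_, dims)
  out <- list(mmf_map = empty, t2mm_map = empty, exch_map = empty,
              t1_map = empty, quality_map = empty, mask = mask)
  idx <- which(mask, arr.ind = TRUE)
  n_fail <- 0
  np <- length(protocol$powers_deg)
  no <- length(protocol$offsets_khz)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]; s <- idx[k, 3]
    sig <- volumes[i, j, s, ]
    ref <- if (is.null(s0_map)) max(sig) else {
      if (length(s0_map) == 1) s0_map else s0_map[i, j, s]
    }
    res <- try({
      vals <- matrix(pmin(pmax(sig / ref, 1e-6), 1.05), np, no)
      sd_ <- saturation_data(vals, protocol, s0_reference = ref, noisy = TRUE)
      fit_two_pool(sd_, t1_obs_ms = t1_map[i, j, s], ...)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      n_fail <- n_fail + 1
      next
    }
    out$mmf_map[i, j, s] <- res$params$mmf
    out$t2mm_map[i, j, s] <- res$params$t2_mm_us
    out$exch_map[i, j, s] <- res$params$exch_rate
    out$t1_map[i, j, s] <- t1_map[i, j, s]
    out$quality_map[i, j, s] <- res$residual_norm
  }
  if (n_fail > 0.5 * nrow(idx)) {
    warning(n_fail, " of ", nrow(idx), " voxel fits failed")
  }
  structure(out, class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  n <- sum(x$mask)
  ok <- sum(!is.na(x$mmf_map))
  cat(sprintf("Parameter map: %d/%d in-mask voxels fitted; median MMF %.1f%%\n",
              ok, n, 100 * stats::median(x$mmf_map, na.rm = TRUE)))
  invisible(x)
}
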