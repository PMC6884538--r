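#' Two-pool tissue parameters for one voxel or ROI
#'
#' The parameter vector of the two-pool magnetization-transfer model: a
#' free-water proton pool observed directly and a macromolecular (semi-solid,
#' mostly collagen in tendon) proton pool observed only through exchange.
#'
#' @param mmf Macromolecular proton fraction, dimensionless in \[0, 1\]
#'   (reported as percent elsewhere; stored as a fraction).
#' @param t2_mm_us Transverse relaxation time of the macromolecular pool,
#'   microseconds. Must be shorter than the water-pool T2.
#' @param t2_w_ms Transverse relaxation time of the water pool, milliseconds.
#' @param t1_obs_ms Observed (single-exponential) longitudinal relaxation
#'   time, milliseconds; measured separately by the VTR fit and held fixed
#'   during MT fitting.
#' @param exch_rate Macromolecular-to-water exchange rate constant
#'   (`R * M0_water`), 1/s.
#' @param s0 Unsaturated equilibrium signal amplitude, arbitrary units.
#'
#' @return An object of class `tissue_params` (a named list).
#' @export
tissue_params <- function(mmf, t2_mm_us, t2_w_ms = 2, t1_obs_ms = 800,
                          exch_rate = 30, s0 = 1) {
  p <- list(mmf = mmf, t2_mm_us = t2_mm_us, t2_w_ms = t2_w_ms,
            t1_obs_ms = t1_obs_ms, exch_rate = exch_rate, s0 = s0)
  validate_tissue_params(p)
  structure(p, class = "tissue_params")
}

validate_tissue_params <- function(p) {
  with(p, {
    if (!is.finite(mmf) || mmf < 0 || mmf > 1) {
      stop("mmf must be a fraction in [0, 1], got ", mmf)
    }
    if (!is.finite(t2_mm_us) || t2_mm_us <= 0) stop("t2_mm_us must be > 0")
    if (!is.finite(t2_w_ms) || t2_w_ms <= 0) stop("t2_w_ms must be > 0")
    if (t2_mm_us >= t2_w_ms * 1000) {
      stop("macromolecular T2 (", t2_mm_us, " us) must be shorter than ",
           "water T2 (", t2_w_ms, " ms): the semi-solid pool is the ",
           "short-T2 pool")
    }
    if (!is.finite(t1_obs_ms) || t1_obs_ms <= 0) stop("t1_obs_ms must be > 0")
    if (!is.finite(exch_rate) || exch_rate < 0) stop("exch_rate must be >= 0")
    if (!is.finite(s0) || s0 <= 0) stop("s0 must be > 0")
  })
  invisible(p)
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "Two-pool tissue parameters:\n  MMF %.1f%%  T2mm %.2f us  T2w %.2f ms  T1obs %.0f ms  k %.1f /s  S0 %.3g\n",
    100 * x$mmf, x$t2_mm_us, x$t2_w_ms, x$t1_obs_ms, x$exch_rate, x$s0))
  invisible(x)
}

#' Normalized saturation data over a power-by-offset grid
#'
#' Container for the measured (or simulated) MT-weighted signal, normalized
#' by the unsaturated amplitude and arranged on the protocol's grid of
#' saturation powers (rows) by frequency offsets (columns).
#'
#' @param values Numeric matrix of S/S0 values, `length(powers)` rows by
#'   `length(offsets)` columns, dimnames set from the protocol. Noiseless
#'   model values lie strictly in (0, 1]; noisy magnitude data may exceed 1
#'   slightly (up to 1.05 tolerated).
#' @param protocol The owning [mt_protocol].
#' @param s0_reference The normalization amplitude, arbitrary units.
#' @param noisy Logical; if `TRUE` the upper bound check is relaxed to 1.05.
#' @return An object of class `saturation_data`.
#' @export
saturation_data <- function(values, protocol, s0_reference = 1,
                            noisy = FALSE) {
  stopifnot(inherits(protocol, "mt_protocol"), is.matrix(values))
  if (!all(dim(values) == c(length(protocol$powers_deg),
                            length(protocol$offsets_khz)))) {
    stop("values must be a ", length(protocol$powers_deg), " x ",
         length(protocol$offsets_khz), " matrix matching the protocol grid")
  }
  upper <- if (noisy) 1.05 else 1
  if (any(!is.finite(values)) || any(values <= 0) || any(values > upper)) {
    stop("saturation values must lie in (0, ", upper, "]")
  }
  dimnames(values) <- list(power_deg = protocol$powers_deg,
                           offset_khz = protocol$offsets_khz)
  structure(list(values = values, protocol = protocol,
                 s0_reference = s0_reference, noisy = noisy),
            class = "saturation_data")
}

#' @export
print.saturation_data <- function(x, ...) {
  cat("Normalized MT saturation data (S/S0):\n")
  print(round(x$values, 4))
  invisible(x)
}
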