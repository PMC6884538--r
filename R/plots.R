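#' Boxplot of macromolecular fraction by cohort and tendon
#'
#' Median/quartile boxplots of the reader-averaged per-subject MMF, one box
#' per cohort-by-tendon group with outliers marked, the standard display of
#' the age comparison.
#'
#' @param per_subject Reader-averaged per-subject table (the `per_subject`
#'   element of [summarize_cohort()]).
#' @param file Optional path; when given the plot is saved (device chosen
#'   from the extension) and the path returned.
#' @return The ggplot object (invisibly when `file` is given).
#' @export
plot_mmf_boxplot <- function(per_subject, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- per_subject
  df$mmf_pct <- 100 * df$mmf_frac
  df$cohort <- factor(df$cohort, levels = c("young", "elderly"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tendon, y = .data$mmf_pct,
                                        fill = .data$cohort)) +
    ggplot2::geom_boxplot(outlier.shape = 3, position =
                            ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "MMF (%)", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Saturation-curve plot for one ROI fit
#'
#' Measured normalized signals (points) against the fitted two-pool model
#' (lines) as a function of frequency offset, one curve per saturation
#' power.
#'
#' @param data The fitted [saturation_data].
#' @param fit The `fit_result` from [fit_two_pool()].
#' @param file Optional output path.
#' @return The ggplot object.
#' @export
plot_saturation_fit <- function(data, fit, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  protocol <- data$protocol
  obs <- data.frame(
    power = factor(rep(protocol$powers_deg, length(protocol$offsets_khz))),
    offset = rep(protocol$offsets_khz, each = length(protocol$powers_deg)),
    signal = as.vector(data$values))
  dense_off <- exp(seq(log(min(protocol$offsets_khz)),
                       log(max(protocol$offsets_khz)), length.out = 40))
  dense_protocol <- mt_protocol(protocol$powers_deg, dense_off,
                                pulse_duration_ms = protocol$pulse_duration_ms,
                                tr_prep_ms = protocol$tr_prep_ms,
                                spokes_per_prep = protocol$spokes_per_prep,
                                fa_deg = protocol$fa_deg,
                                te_ms = protocol$te_ms)
  model <- forward_signal(fit$params, dense_protocol)
  scale <- fit$params$s0 / data$s0_reference
  fitdf <- data.frame(
    power = factor(rep(dense_protocol$powers_deg, length(dense_off))),
    offset = rep(dense_off, each = length(dense_protocol$powers_deg)),
    signal = scale * as.vector(model$values))
  p <- ggplot2::ggplot(obs, ggplot2::aes(x = .data$offset, y = .data$signal,
                                         colour = .data$power)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitdf) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency offset (kHz)", y = expression(S / S[0]),
                  colour = "Power (deg)",
                  subtitle = sprintf("MMF %.1f%%, T2mm %.1f us",
                                     100 * fit$params$mmf,
                                     fit$params$t2_mm_us)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
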