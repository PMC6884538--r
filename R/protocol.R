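#' MT saturation protocol
#'
#' Describes the pulsed off-resonance saturation schedule of a UTE
#' magnetization-transfer acquisition: the grid of Fermi saturation pulse
#' powers and frequency offsets, the pulse and preparation-cycle timing, and
#' the readout that follows each preparation.
#'
#' @param powers_deg Numeric vector of saturation pulse powers (total flip
#'   angle of the Fermi pulse), degrees. All entries must be positive.
#' @param offsets_khz Numeric vector of saturation frequency offsets, kHz.
#'   All entries must be positive; offsets below 0.5 kHz are rejected because
#'   the macromolecular lineshape is singular on resonance.
#' @param pulse_duration_ms Duration of the Fermi saturation pulse, ms.
#' @param tr_prep_ms Duration of one MT preparation cycle (saturation pulse
#'   plus readout spokes), ms. Must exceed `pulse_duration_ms`.
#' @param spokes_per_prep Number of UTE readout spokes acquired after each
#'   saturation pulse.
#' @param fa_deg Excitation flip angle of the readout, degrees.
#' @param te_ms Echo time, ms.
#' @param pulse_shape Saturation pulse shape identifier; only `"fermi"` is
#'   implemented.
#'
#' @return An object of class `mt_protocol`: a list with the fields above and
#'   `n_conditions`, the size of the power-by-offset grid.
#' @seealso [default_mt_protocol()], [forward_signal()]
#' @export
mt_protocol <- function(powers_deg, offsets_khz,
                        pulse_duration_ms = 8,
                        tr_prep_ms = 40.6,
                        spokes_per_prep = 9,
                        fa_deg = 7,
                        te_ms = 0.032,
                        pulse_shape = "fermi") {
  stopifnot(is.numeric(powers_deg), length(powers_deg) >= 1,
            is.numeric(offsets_khz), length(offsets_khz) >= 1)
  if (any(powers_deg <= 0)) stop("all saturation powers must be > 0 degrees")
  if (any(offsets_khz <= 0)) stop("all frequency offsets must be > 0 kHz")
  if (any(offsets_khz < 0.5)) {
    stop("offsets below 0.5 kHz are outside the validity of the ",
         "Super-Lorentzian lineshape (on-resonance singularity)")
  }
  if (anyDuplicated(powers_deg) || anyDuplicated(offsets_khz)) {
    stop("powers and offsets must be unique")
  }
  if (!identical(tolower(pulse_shape), "fermi")) {
    stop("unsupported pulse_shape: ", pulse_shape)
  }
  stopifnot(pulse_duration_ms > 0, tr_prep_ms > pulse_duration_ms,
            spokes_per_prep >= 1, fa_deg > 0, te_ms >= 0)
  structure(list(
    powers_deg = as.numeric(sort(powers_deg)),
    offsets_khz = as.numeric(sort(offsets_khz)),
    pulse_duration_ms = pulse_duration_ms,
    tr_prep_ms = tr_prep_ms,
    spokes_per_prep = spokes_per_prep,
    fa_deg = fa_deg,
    te_ms = te_ms,
    pulse_shape = "fermi",
    n_conditions = length(powers_deg) * length(offsets_khz)
  ), class = "mt_protocol")
}

#' Default 3T UTE-MT tendon protocol
#'
#' The saturation schedule used throughout this package's simulations:
#' Fermi pulse powers 500/1000/1500 degrees crossed with frequency offsets
#' 2/5/10/20/50 kHz, an 8 ms saturation pulse, 9 readout spokes per
#' preparation and a 7 degree excitation.
#'
#' @return An [mt_protocol] object.
#' @export
default_mt_protocol <- function() {
  mt_protocol(powers_deg = c(500, 1000, 1500),
              offsets_khz = c(2, 5, 10, 20, 50))
}

#' Variable-TR / AFI T1 protocol
#'
#' Timing of the T1 acquisition: a variable-TR (VTR) saturation-recovery
#' series plus an optional dual-TR actual-flip-angle (AFI) pair used to
#' correct the nominal excitation angle for B1 inhomogeneity.
#'
#' @param vtr_trs_ms Repetition times of the VTR series, ms (>= 3 values,
#'   strictly increasing).
#' @param fa_deg Nominal excitation flip angle, degrees.
#' @param afi_trs_ms Length-2 vector of AFI repetition times, ms
#'   (`NULL` to disable the AFI correction).
#' @param te_ms Echo time, ms.
#' @return An object of class `vtr_protocol`.
#' @export
vtr_protocol <- function(vtr_trs_ms = c(20, 80, 150), fa_deg = 45,
                         afi_trs_ms = c(20, 100), te_ms = 0.032) {
  stopifnot(length(vtr_trs_ms) >= 3, all(diff(vtr_trs_ms) > 0),
            all(vtr_trs_ms > 0), fa_deg > 0)
  if (!is.null(afi_trs_ms)) {
    stopifnot(length(afi_trs_ms) == 2, afi_trs_ms[2] > afi_trs_ms[1],
              afi_trs_ms[1] > 0)
  }
  structure(list(vtr_trs_ms = as.numeric(vtr_trs_ms), fa_deg = fa_deg,
                 afi_trs_ms = afi_trs_ms, te_ms = te_ms),
            class = "vtr_protocol")
}

#' Read or write an MT protocol as a YAML config file
#'
#' The on-disk form is a flat key-value mapping (`powers_deg`, `offsets_khz`,
#' `pulse_duration_ms`, `tr_prep_ms`, `spokes_per_prep`, `fa_deg`, `te_ms`).
#'
#' @param path File path.
#' @return `read_mt_protocol` returns an [mt_protocol]; `write_mt_protocol`
#'   returns `path` invisibly.
#' @export
read_mt_protocol <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("powers_deg", "offsets_khz")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("protocol config ", path, " is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  mt_protocol(powers_deg = cfg$powers_deg,
              offsets_khz = cfg$offsets_khz,
              pulse_duration_ms = cfg$pulse_duration_ms %||% 8,
              tr_prep_ms = cfg$tr_prep_ms %||% 40.6,
              spokes_per_prep = cfg$spokes_per_prep %||% 9,
              fa_deg = cfg$fa_deg %||% 7,
              te_ms = cfg$te_ms %||% 0.032)
}

#' @rdname read_mt_protocol
#' @param protocol An [mt_protocol] object.
#' @export
write_mt_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "mt_protocol"))
  yaml::write_yaml(protocol[c("powers_deg", "offsets_khz",
                              "pulse_duration_ms", "tr_prep_ms",
                              "spokes_per_prep", "fa_deg", "te_ms")], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mt_protocol <- function(x, ...) {
  cat("MT protocol (", x$pulse_shape, " pulse):\n", sep = "")
  cat("  powers:  ", paste0(x$powers_deg, "°", collapse = ", "), "\n")
  cat("  offsets: ", paste(x$offsets_khz, collapse = ", "), "kHz\n")
  cat("  pulse", x$pulse_duration_ms, "ms /", x$tr_prep_ms,
      "ms prep,", x$spokes_per_prep, "spokes, FA", x$fa_deg, "°\n")
  invisible(x)
}
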