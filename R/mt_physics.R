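#' Super-Lorentzian absorption lineshape
#'
#' Orientationally averaged absorption lineshape of the semi-solid
#' macromolecular proton pool,
#' \deqn{g(\Delta, T_{2mm}) = \int_0^{\pi/2} \sin\theta \sqrt{2/\pi}
#'   \frac{T_{2mm}}{|3\cos^2\theta - 1|}
#'   \exp\!\left(-2\left(\frac{2\pi\Delta\,T_{2mm}}{3\cos^2\theta-1}\right)^2\right)
#'   d\theta,}
#' evaluated by adaptive quadrature with the integration domain split at the
#' magic angle \eqn{\theta_m = \arccos(1/\sqrt{3})}, where the integrand has
#' an integrable (exponentially suppressed) singularity.
#'
#' The lineshape diverges as the offset approaches resonance; offsets below
#' 500 Hz are rejected. It is symmetric in the sign of the offset, so only
#' non-negative offsets are accepted.
#'
#' @param offset_hz Frequency offset(s) from water resonance, Hz (>= 500).
#' @param t2_mm_s Macromolecular T2, seconds (e.g. `7.3e-6`).
#' @return Absorption value(s) in seconds, one per offset; strictly positive
#'   and non-increasing in offset over the off-resonance regime.
#' @examples
#' superlorentzian_lineshape(10e3, 7.3e-6)
#' @export
superlorentzian_lineshape <- function(offset_hz, t2_mm_s) {
  stopifnot(is.numeric(offset_hz), length(t2_mm_s) == 1, t2_mm_s > 0)
  if (any(offset_hz < 500)) {
    stop("offset_hz below the 500 Hz on-resonance cutoff: the ",
         "Super-Lorentzian lineshape is singular near resonance")
  }
  vapply(offset_hz, function(d) .superlorentzian1(d, t2_mm_s), numeric(1))
}

.magic_theta <- acos(1 / sqrt(3))

.superlorentzian1 <- function(delta, t2) {
  integrand <- function(theta) {
    u <- 3 * cos(theta)^2 - 1
    x <- 2 * pi * delta * t2 / u
    sin(theta) * sqrt(2 / pi) * (t2 / abs(u)) * exp(-2 * x^2)
  }
  v1 <- stats::integrate(integrand, 0, .magic_theta,
                         abs.tol = 1e-12, rel.tol = 1e-10,
                         subdivisions = 500L)
  v2 <- stats::integrate(integrand, .magic_theta, pi / 2,
                         abs.tol = 1e-12, rel.tol = 1e-10,
                         subdivisions = 500L)
  if (v1$message != "OK" || v2$message != "OK") {
    stop("lineshape quadrature failed to converge at offset ", delta, " Hz")
  }
  v1$value + v2$value
}

#' Continuous-wave power equivalent of the pulsed Fermi saturation
#'
#' Reduces the pulsed saturation train to an equivalent continuous-wave
#' amplitude (the modified-rectangular-pulse treatment): the returned
#' \eqn{\omega_{1,CWPE}} is the constant B1 amplitude whose mean-square
#' saturation power over one preparation period equals that of the Fermi
#' pulse. The Fermi envelope used has a flat top of half-width 0.35 times
#' the pulse duration and a transition width of 1/60 of the duration; its
#' area and power shape factors are evaluated by numerical quadrature.
#'
#' The flip-angle-to-amplitude conversion (degrees to rad/s) happens here
#' and nowhere else.
#'
#' @param sat_power_deg Total flip angle of the saturation pulse, degrees
#'   (>= 0; 0 returns 0).
#' @param pulse_duration_ms Fermi pulse duration, ms.
#' @param tr_prep_ms Preparation period over which the power is averaged, ms.
#'   Must exceed the pulse duration (duty cycle < 1).
#' @return \eqn{\omega_{1,CWPE}} in rad/s. Linear in `sat_power_deg` and
#'   proportional to the square root of the duty cycle.
#' @examples
#' cw_power_equivalent(1000, 8, 40.6)
#' @export
cw_power_equivalent <- function(sat_power_deg, pulse_duration_ms,
                                tr_prep_ms) {
  stopifnot(sat_power_deg >= 0, pulse_duration_ms > 0, tr_prep_ms > 0)
  if (pulse_duration_ms >= tr_prep_ms) {
    stop("duty cycle >= 1: pulse_duration_ms must be < tr_prep_ms")
  }
  if (sat_power_deg == 0) return(0)
  sf <- .fermi_shape_factors()
  tau_s <- pulse_duration_ms / 1000
  tr_s <- tr_prep_ms / 1000
  w1max <- (sat_power_deg * pi / 180) / (sf$p1 * tau_s)
  w1max * sqrt(sf$p2 * tau_s / tr_s)
}

# Area (p1) and power (p2) shape factors of the unit-amplitude Fermi
# envelope f(t) = 1/(1 + exp((|t - 1/2| - 0.35)/(1/60))) on [0, 1].
# Scale-invariant, so computed once on the unit interval and cached.
.fermi_cache <- new.env(parent = emptyenv())
.fermi_shape_factors <- function() {
  if (is.null(.fermi_cache$sf)) {
    f <- function(t) 1 / (1 + exp((abs(t - 0.5) - 0.35) * 60))
    p1 <- stats::integrate(f, 0, 1, abs.tol = 1e-13)$value
    p2 <- stats::integrate(function(t) f(t)^2, 0, 1, abs.tol = 1e-13)$value
    .fermi_cache$sf <- list(p1 = p1, p2 = p2)
  }
  .fermi_cache$sf
}

# Longitudinal rate of the water pool recovered from the observed
# (single-exponential) R1: the observed rate is the slow eigenvalue of the
# coupled two-pool longitudinal system, inverted for the free-pool rate.
.water_r1 <- function(r1_obs, f, exch_rate, r1_mm = 1) {
  ka <- exch_rate * f / (1 - f)   # water -> macromolecular
  kb <- exch_rate                 # macromolecular -> water
  r1_obs - ka * (r1_mm - r1_obs) / (r1_mm - r1_obs + kb)
}

#' Two-pool steady-state MT signal
#'
#' Forward model for the normalized saturated signal under pulsed
#' off-resonance irradiation, in the continuous-wave-power-equivalent
#' steady-state form: the macromolecular pool is saturated at rate
#' \eqn{R_{rf,mm} = \pi \omega_{1,CWPE}^2 \, g(\Delta, T_{2mm})} with the
#' Super-Lorentzian lineshape, the water pool experiences off-resonance
#' direct saturation through the Lorentzian term
#' \eqn{(\omega_{1,CWPE}/2\pi\Delta)^2 / (R_{1w} T_{2w})}, the pools exchange
#' at `exch_rate`, and the water-pool longitudinal rate is recovered from
#' the separately measured observed T1 (macromolecular-pool R1 fixed at
#' 1/s, the conventional choice where it is unidentifiable).
#'
#' @param params A [tissue_params] object.
#' @param protocol An [mt_protocol] object.
#' @param r1_mm Longitudinal rate of the macromolecular pool, 1/s.
#' @return A [saturation_data] with model values in (0, 1], non-increasing
#'   in power at fixed offset and non-decreasing in offset at fixed power.
#' @examples
#' forward_signal(tissue_params(mmf = 0.17, t2_mm_us = 7.3),
#'                default_mt_protocol())
#' @export
forward_signal <- function(params, protocol, r1_mm = 1) {
  stopifnot(inherits(protocol, "mt_protocol"))
  if (!inherits(params, "tissue_params")) params <- do.call(tissue_params, params)
  validate_tissue_params(params)
  vals <- .two_pool_grid(
    mmf = params$mmf, t2_mm_us = params$t2_mm_us, t2_w_ms = params$t2_w_ms,
    t1_obs_ms = params$t1_obs_ms, exch_rate = params$exch_rate,
    protocol = protocol, r1_mm = r1_mm)
  saturation_data(vals, protocol, s0_reference = params$s0)
}

# Core grid evaluation on raw numerics (also the fitting residual kernel).
.two_pool_grid <- function(mmf, t2_mm_us, t2_w_ms, t1_obs_ms, exch_rate,
                           protocol, r1_mm = 1) {
  powers <- protocol$powers_deg
  offsets_hz <- protocol$offsets_khz * 1000
  f <- min(max(mmf, 1e-9), 1 - 1e-9)   # guard the f/(1-f) pole at the bounds
  t2b <- t2_mm_us * 1e-6
  t2a <- t2_w_ms / 1000
  r1_obs <- 1000 / t1_obs_ms
  kb <- exch_rate
  ka <- exch_rate * f / (1 - f)
  ra <- .water_r1(r1_obs, f, exch_rate, r1_mm)
  ra <- max(ra, 1e-3)
  g <- vapply(offsets_hz, .superlorentzian1, numeric(1), t2 = t2b)
  w1 <- vapply(powers, cw_power_equivalent, numeric(1),
               pulse_duration_ms = protocol$pulse_duration_ms,
               tr_prep_ms = protocol$tr_prep_ms)
  vals <- matrix(NA_real_, length(powers), length(offsets_hz))
  for (i in seq_along(powers)) {
    rrfb <- pi * w1[i]^2 * g
    ds <- (w1[i] / (2 * pi * offsets_hz))^2 / (ra * t2a)
    num <- r1_mm * (ka / ra) + rrfb + r1_mm + kb
    den <- (ka / ra) * (r1_mm + rrfb) + (1 + ds) * (rrfb + r1_mm + kb)
    vals[i, ] <- num / den
  }
  vals
}

#' Add Rician magnitude noise to saturation data
#'
#' Applies the magnitude-MRI noise model: each underlying signal
#' \eqn{v} becomes \eqn{\sqrt{(v + n_1)^2 + n_2^2}} with \eqn{n_1, n_2}
#' independent zero-mean Gaussians of standard deviation
#' `s0_reference / snr`, then is renormalized by `s0_reference`.
#'
#' @param data A [saturation_data] object.
#' @param snr Signal-to-noise ratio of the unsaturated signal
#'   (`s0_reference / sigma`); `Inf` returns the input unchanged.
#' @param seed Integer seed; the same seed always reproduces the same noise.
#' @return A [saturation_data] with `noisy = TRUE`.
#' @export
add_rician_noise <- function(data, snr, seed) {
  stopifnot(inherits(data, "saturation_data"), snr > 0)
  if (is.infinite(snr)) return(data)
  v <- data$values * data$s0_reference
  noisy <- with_seed_(as.integer(seed), {
    rician_transform(v, sigma = data$s0_reference / snr)
  })
  noisy <- noisy / data$s0_reference
  noisy <- pmin(noisy, 1.05)   # container bound for magnitude overshoot
  saturation_data(matrix(noisy, nrow(v), ncol(v)), data$protocol,
                  s0_reference = data$s0_reference, noisy = TRUE)
}

#' Rician magnitude transform of a signal array
#'
#' Low-level kernel used by [add_rician_noise()] and the phantom generator:
#' draws the two Gaussian quadrature components at the current RNG state.
#'
#' @param v Numeric array of noiseless magnitudes.
#' @param sigma Gaussian standard deviation per quadrature channel.
#' @return Array of the same shape with Rician-distributed magnitudes.
#' @keywords internal
rician_transform <- function(v, sigma) {
  n1 <- stats::rnorm(length(v), 0, sigma)
  n2 <- stats::rnorm(length(v), 0, sigma)
  out <- sqrt((v + n1)^2 + n2^2)
  array(out, dim = if (is.null(dim(v))) length(v) else dim(v))
}

# Evaluate expr with a local, restored RNG state.
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
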