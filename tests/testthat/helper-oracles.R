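# Frozen reference values computed with an independent adaptive-quadrature
# implementation (SciPy quad, abs tol 1e-15) of the same integrals, before
# the package implementation was written.

# Super-Lorentzian g(offset, T2mm) in seconds, T2mm = 7.3 us
SL_ORACLE <- c(
  "2"  = 8.294346956694e-06,
  "5"  = 5.076024619419e-06,
  "10" = 2.588602139081e-06,
  "20" = 6.274733646339e-07,
  "50" = 1.062893900944e-08
)
SL_ORACLE_10K_10US <- 2.138321353939e-06
SL_ORACLE_20K_5US  <- 1.069160676969e-06

# CW power equivalent of a 1000 deg, 8 ms Fermi pulse in a 40.6 ms
# preparation period (direct numerical integral of the pulse envelope)
CWPE_ORACLE_1000_8_406 <- 1129.6092492578

# Two-pool steady-state grid (powers 500/1000/1500 deg x offsets
# 2/5/10/20/50 kHz) at MMF 0.17, T2mm 7.3 us, T2w 2 ms, T1obs 800 ms,
# exchange 30 1/s, from an independent implementation of the
# CW-power-equivalent steady-state expression.
RAMANI_ORACLE_GRID <- matrix(c(
  0.3870039086, 0.5888331482, 0.7424760629, 0.9187637869, 0.9975212932,
  0.1621457681, 0.3156537736, 0.4599588765, 0.7475195737, 0.9901627132,
  0.0919054072, 0.2125640163, 0.3202076498, 0.5856455937, 0.9781508759
), nrow = 3, byrow = TRUE)

# Closed-form mean of a Rician variate with noncentrality v and scale sigma:
# sigma * sqrt(pi/2) * L_{1/2}(-v^2 / (2 sigma^2)) via Bessel functions.
rician_mean_analytic <- function(v, sigma) {
  x <- -v^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) -
                            x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}

# Brute-force two-sided Mann-Whitney p-value by enumerating every
# assignment of the pooled ranks to group A (ties not supported).
wilcoxon_exact_bruteforce <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Forward-simulated dual-TR AFI steady-state signal pair (the oracle for
# the actual-flip-angle relation).
afi_signals_oracle <- function(t1_ms, fa_deg, tr1_ms, tr2_ms) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr1_ms / t1_ms); e2 <- exp(-tr2_ms / t1_ms)
  den <- 1 - e1 * e2 * cos(a)^2
  c(sin(a) * (1 - e2 + (1 - e1) * e2 * cos(a)) / den,
    sin(a) * (1 - e1 + (1 - e2) * e1 * cos(a)) / den)
}

# Random valid tissue parameters within the fitting bounds (away from the
# edges so noiseless recovery is well-posed).
random_tissue_params <- function() {
  tissue_params(
    mmf = stats::runif(1, 0.05, 0.4),
    t2_mm_us = stats::runif(1, 4, 15),
    t2_w_ms = stats::runif(1, 1, 20),
    t1_obs_ms = stats::runif(1, 400, 1500),
    exch_rate = stats::runif(1, 10, 60),
    s0 = 1)
}
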