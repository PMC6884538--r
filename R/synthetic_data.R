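#' Reference tendon parameter distributions
#'
#' Per-cohort, per-tendon means and SDs of the observed T1 (ms), the
#' macromolecular proton fraction (percent) and the macromolecular T2
#' (microseconds) used as the default generating distributions for
#' synthetic cohorts: young/elderly anterior (ATT) and posterior (PTT)
#' tibialis tendon values measured at 3T.
#'
#' @return A data.frame with columns `cohort`, `tendon`, `t1_mean`, `t1_sd`,
#'   `mmf_pct_mean`, `mmf_pct_sd`, `t2mm_mean`, `t2mm_sd`.
#' @export
tendon_reference_table <- function() {
  data.frame(
    cohort = rep(c("young", "elderly"), each = 2),
    tendon = rep(c("ATT", "PTT"), 2),
    t1_mean = c(823, 735, 789, 762),
    t1_sd = c(156, 86, 154, 123),
    mmf_pct_mean = c(17.0, 21.3, 14.1, 16.4),
    mmf_pct_sd = c(5.0, 4.8, 3.9, 3.3),
    t2mm_mean = c(7.3, 7.3, 7.3, 7.1),
    t2mm_sd = c(0.2, 0.2, 0.3, 0.3)
  )
}

#' Synthetic cohort specification
#'
#' Bundles everything the generator needs: the per-(cohort, tendon)
#' parameter distributions, cohort sizes, image SNR, reader model and seed.
#' Defaults reproduce the study conditions: 26 young and 22 elderly
#' subjects drawn from [tendon_reference_table()], image SNR 50, three
#' readers with 1-voxel ROI boundary jitter. The exchange rate and water T2
#' are not part of the reference table (they are nuisance parameters of the
#' forward model); their generating distributions are 30 +/- 5 1/s and
#' 2 +/- 0.3 ms, mid-range tendon values.
#'
#' @param distributions Data.frame in the layout of
#'   [tendon_reference_table()].
#' @param n_young,n_elderly Cohort sizes.
#' @param snr Image signal-to-noise ratio of the simulated volumes.
#' @param n_readers Number of simulated ROI readers.
#' @param reader_jitter_vox ROI boundary perturbation magnitude, voxels.
#' @param reader_noise_sd Additive per-reader measurement noise used by the
#'   parameter-level reader simulator, in the parameter's own units.
#' @param att_ptt_cor Within-subject correlation between ATT and PTT draws
#'   of each parameter.
#' @param exch_mean,exch_sd Exchange-rate generating distribution, 1/s.
#' @param t2w_mean,t2w_sd Water-T2 generating distribution, ms.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(distributions = tendon_reference_table(),
                        n_young = 26, n_elderly = 22,
                        snr = 50, n_readers = 3,
                        reader_jitter_vox = 1, reader_noise_sd = 0.005,
                        att_ptt_cor = 0.5,
                        exch_mean = 30, exch_sd = 5,
                        t2w_mean = 2, t2w_sd = 0.3,
                        seed = 1L) {
  stopifnot(n_young >= 1, n_elderly >= 1, snr > 0, n_readers >= 1,
            reader_jitter_vox >= 0, att_ptt_cor >= -1, att_ptt_cor <= 1)
  sds <- unlist(distributions[c("t1_sd", "mmf_pct_sd", "t2mm_sd")])
  if (any(sds < 0) || exch_sd < 0 || t2w_sd < 0 || reader_noise_sd < 0) {
    stop("all SDs must be >= 0")
  }
  structure(list(distributions = distributions,
                 n_young = n_young, n_elderly = n_elderly,
                 snr = snr, n_readers = n_readers,
                 reader_jitter_vox = reader_jitter_vox,
                 reader_noise_sd = reader_noise_sd,
                 att_ptt_cor = att_ptt_cor,
                 exch_mean = exch_mean, exch_sd = exch_sd,
                 t2w_mean = t2w_mean, t2w_sd = t2w_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Inverse-CDF truncated normal draw; exact for sd = 0.
rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Correlated pair of truncated normal draws (one per tendon) sharing a
# latent bivariate-normal structure; out-of-bound pairs are redrawn.
rtrunc_pair_ <- function(n, mean1, sd1, mean2, sd2, rho, lo, hi) {
  out1 <- numeric(n); out2 <- numeric(n)
  todo <- seq_len(n)
  for (iter in 1:1000) {
    m <- length(todo)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    x1 <- mean1 + sd1 * z1
    x2 <- mean2 + sd2 * z2
    ok <- x1 >= lo & x1 <= hi & x2 >= lo & x2 <= hi
    out1[todo[ok]] <- x1[ok]
    out2[todo[ok]] <- x2[ok]
    todo <- todo[!ok]
    if (!length(todo)) break
  }
  if (length(todo)) stop("truncated-normal rejection sampling did not finish")
  list(out1, out2)
}

#' Draw a synthetic cohort of per-subject tendon parameters
#'
#' Samples each subject's ATT and PTT two-pool parameters from truncated
#' normal distributions with the spec's means and SDs (truncation at
#' physical bounds: MMF in (0.1, 90) percent, T1 in (100, 5000) ms, T2mm in
#' (1, 50) microseconds, exchange in (1, 100) 1/s, water T2 in (0.1, 100)
#' ms), with the spec's ATT-PTT within-subject correlation. Reproducible:
#' the same spec and seed always give the same cohort.
#'
#' @param spec A [cohort_spec].
#' @param seed Optional seed overriding `spec$seed`.
#' @return Data.frame with one row per subject x tendon: `subject_id`,
#'   `cohort`, `tendon`, `mmf_frac`, `t1_ms`, `t2mm_us`, `exch_rate`,
#'   `t2w_ms`.
#' @export
sample_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed_(as.integer(seed), {
    rows <- list()
    for (co in c("young", "elderly")) {
      n <- if (co == "young") spec$n_young else spec$n_elderly
      d <- spec$distributions
      att <- d[d$cohort == co & d$tendon == "ATT", ]
      ptt <- d[d$cohort == co & d$tendon == "PTT", ]
      rho <- spec$att_ptt_cor
      mmf <- rtrunc_pair_(n, att$mmf_pct_mean, att$mmf_pct_sd,
                          ptt$mmf_pct_mean, ptt$mmf_pct_sd, rho, 0.1, 90)
      t1 <- rtrunc_pair_(n, att$t1_mean, att$t1_sd,
                         ptt$t1_mean, ptt$t1_sd, rho, 100, 5000)
      t2mm <- rtrunc_pair_(n, att$t2mm_mean, att$t2mm_sd,
                           ptt$t2mm_mean, ptt$t2mm_sd, rho, 1, 50)
      exch <- rtrunc_pair_(n, spec$exch_mean, spec$exch_sd,
                           spec$exch_mean, spec$exch_sd, rho, 1, 100)
      t2w <- rtrunc_pair_(n, spec$t2w_mean, spec$t2w_sd,
                          spec$t2w_mean, spec$t2w_sd, rho, 0.1, 100)
      ids <- sprintf("%s%02d", if (co == "young") "Y" else "E", seq_len(n))
      for (ti in 1:2) {
        rows[[paste(co, ti)]] <- data.frame(
          subject_id = ids, cohort = co,
          tendon = c("ATT", "PTT")[ti],
          mmf_frac = mmf[[ti]] / 100,
          t1_ms = t1[[ti]],
          t2mm_us = t2mm[[ti]],
          exch_rate = exch[[ti]],
          t2w_ms = t2w[[ti]])
      }
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    out[order(out$cohort, out$subject_id, out$tendon), ]
  })
}

#' Parameter-level reader measurements
#'
#' Simulates independent readers re-measuring the same per-subject values:
#' each reader's measurement is the true value plus zero-mean Gaussian noise
#' of SD `noise_sd` (reader placement and measurement variability collapsed
#' to one scalar). Used for reader-agreement analyses that do not need the
#' imaging pipeline.
#'
#' @param true_values Numeric vector of per-subject true values.
#' @param n_readers Number of readers.
#' @param noise_sd Per-reader measurement SD, same units as the values.
#' @param seed Integer seed.
#' @return Matrix, subjects in rows and readers in columns.
#' @export
simulate_reader_measurements <- function(true_values, n_readers, noise_sd,
                                         seed) {
  stopifnot(n_readers >= 1, noise_sd >= 0)
  with_seed_(as.integer(seed), {
    n <- length(true_values)
    true_values + matrix(stats::rnorm(n * n_readers, 0, noise_sd),
                         n, n_readers)
  })
}

# Elliptical cylinder mask through all slices.
.ellipse_mask <- function(dims, center, radii) {
  xy <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  inside <- ((xy$x - center[1]) / radii[1])^2 +
    ((xy$y - center[2]) / radii[2])^2 <= 1
  array(rep(inside, dims[3]), dim = dims)
}

.afi_pair_signal <- function(t1_ms, fa_deg, tr1_ms, tr2_ms, s0 = 1) {
  a <- fa_deg * pi / 180
  e1 <- exp(-tr1_ms / t1_ms); e2 <- exp(-tr2_ms / t1_ms)
  den <- 1 - e1 * e2 * cos(a)^2
  c(s0 * sin(a) * (1 - e2 + (1 - e1) * e2 * cos(a)) / den,
    s0 * sin(a) * (1 - e1 + (1 - e2) * e1 * cos(a)) / den)
}

#' Generate one subject's synthetic image dataset
#'
#' Builds a small tendon phantom: two elliptical tendon cross-sections
#' (ATT and PTT) embedded in a muscle-like background on a
#' `dims` grid, fills one volume per MT condition with the two-pool
#' steady-state signal, the variable-TR volumes with the saturation-recovery
#' signal and the AFI pair with the dual-TR steady-state signal, then adds
#' Rician noise at the requested SNR.
#'
#' @param att_params,ptt_params [tissue_params] of the two tendons.
#' @param protocol An [mt_protocol].
#' @param vtr An optional [vtr_protocol] (`NULL` skips the T1 volumes).
#' @param snr Image SNR: the brightest tendon signal of each series over
#'   that series' noise SD (each series carries its own receiver scaling);
#'   `Inf` for noiseless volumes.
#' @param seed Integer seed for the noise.
#' @param dims Phantom dimensions (x, y, slices).
#' @param bg_params Background-tissue [tissue_params].
#' @param b1_scale Multiplicative B1 error applied to the excitation angle
#'   of the simulated AFI pair.
#' @param att_center,ptt_center In-plane centers of the two elliptical
#'   tendon cross-sections, voxels.
#' @param att_radii,ptt_radii In-plane semi-axes of the ellipses, voxels.
#' @return List with `mt_stack` (4-D, condition axis in protocol grid
#'   order, power fastest), `vtr_stack`, `afi_stack`, [roi_mask] elements
#'   `att_mask` and `ptt_mask`, and `truth` (the generating parameters).
#' @export
generate_subject_dataset <- function(att_params, ptt_params, protocol,
                                     vtr = vtr_protocol(), snr = 50,
                                     seed = 1L, dims = c(64, 64, 4),
                                     bg_params = tissue_params(
                                       mmf = 0.08, t2_mm_us = 7.3,
                                       t2_w_ms = 25, t1_obs_ms = 1400,
                                       exch_rate = 20, s0 = 1),
                                     b1_scale = 1,
                                     att_center = c(17, 32),
                                     att_radii = c(10, 7),
                                     ptt_center = c(46, 32),
                                     ptt_radii = c(12, 8)) {
  stopifnot(inherits(protocol, "mt_protocol"), length(dims) == 3)
  att_mask <- .ellipse_mask(dims, center = att_center, radii = att_radii)
  ptt_mask <- .ellipse_mask(dims, center = ptt_center, radii = ptt_radii)
  if (any(att_mask & ptt_mask)) stop("tendon regions overlap")
  regions <- list(list(mask = att_mask, p = att_params),
                  list(mask = ptt_mask, p = ptt_params),
                  list(mask = !(att_mask | ptt_mask), p = bg_params))

  nc <- protocol$n_conditions
  mt <- array(0, c(dims, nc))
  for (r in regions) {
    sig <- forward_signal(r$p, protocol)
    v <- r$p$s0 * as.vector(sig$values)
    for (k in seq_len(nc)) {
      plane <- mt[, , , k, drop = FALSE]
      plane[r$mask] <- v[k]
      mt[, , , k] <- plane
    }
  }

  vtr_stack <- NULL; afi_stack <- NULL
  if (!is.null(vtr)) {
    fa_act <- vtr$fa_deg * b1_scale
    amp <- sin(fa_act * pi / 180)
    vtr_stack <- array(0, c(dims, length(vtr$vtr_trs_ms)))
    for (r in regions) {
      v <- r$p$s0 * amp * (1 - exp(-vtr$vtr_trs_ms / r$p$t1_obs_ms))
      for (k in seq_along(v)) {
        plane <- vtr_stack[, , , k, drop = FALSE]
        plane[r$mask] <- v[k]
        vtr_stack[, , , k] <- plane
      }
    }
    if (!is.null(vtr$afi_trs_ms)) {
      afi_stack <- array(0, c(dims, 2))
      for (r in regions) {
        v <- .afi_pair_signal(r$p$t1_obs_ms, fa_act,
                              vtr$afi_trs_ms[1], vtr$afi_trs_ms[2],
                              s0 = r$p$s0)
        for (k in 1:2) {
          plane <- afi_stack[, , , k, drop = FALSE]
          plane[r$mask] <- v[k]
          afi_stack[, , , k] <- plane
        }
      }
    }
  }

  if (is.finite(snr)) {
    # Each series is independently receiver-scaled on a scanner, so the SNR
    # is referenced to the brightest tendon signal of that series.
    tendon <- att_mask | ptt_mask
    series_sigma <- function(stack) {
      max(apply(stack, 4, function(v) max(v[tendon]))) / snr
    }
    noisy <- with_seed_(as.integer(seed), {
      out <- list(mt = rician_transform(mt, series_sigma(mt)))
      if (!is.null(vtr_stack)) {
        out$vtr <- rician_transform(vtr_stack, series_sigma(vtr_stack))
      }
      if (!is.null(afi_stack)) {
        out$afi <- rician_transform(afi_stack, series_sigma(afi_stack))
      }
      out
    })
    mt <- noisy$mt
    if (!is.null(vtr_stack)) vtr_stack <- noisy$vtr
    if (!is.null(afi_stack)) afi_stack <- noisy$afi
  }

  list(mt_stack = mt, vtr_stack = vtr_stack, afi_stack = afi_stack,
       att_mask = roi_mask(att_mask, "ATT"),
       ptt_mask = roi_mask(ptt_mask, "PTT"),
       truth = list(ATT = att_params, PTT = ptt_params, bg = bg_params),
       protocol = protocol, vtr = vtr, snr = snr, b1_scale = b1_scale)
}

# In-plane integer translation of a 3-D logical mask (zero fill).
.shift_mask <- function(mask, dx, dy) {
  d <- dim(mask)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xs_src <- xs - dx; ys_src <- ys - dy
  okx <- xs_src >= 1 & xs_src <= d[1]
  oky <- ys_src >= 1 & ys_src <= d[2]
  out[xs[okx], ys[oky], ] <- mask[xs_src[okx], ys_src[oky], , drop = FALSE]
  out
}

.morph_mask <- function(mask, op) {
  if (op == 0) return(mask)
  kern <- EBImage::makeBrush(3, shape = "box")
  out <- mask
  for (s in seq_len(dim(mask)[3])) {
    sl <- mask[, , s] * 1
    sl <- if (op > 0) EBImage::dilate(sl, kern) else EBImage::erode(sl, kern)
    out[, , s] <- sl > 0.5
  }
  out
}

#' Simulate reader-placed ROI masks
#'
#' Emulates independent readers outlining the same tendon: each reader's
#' mask is the true mask translated in-plane by up to `jitter_vox` voxels
#' and randomly dilated or eroded by one voxel, with a per-reader seeded
#' draw. With zero jitter every reader reproduces the true mask exactly. If
#' a perturbation empties the mask it is regenerated with reduced jitter
#' and a warning.
#'
#' @param true_mask An [roi_mask] (or logical array).
#' @param n_readers Number of readers.
#' @param jitter_vox Maximum in-plane translation, voxels (integer >= 0).
#' @param seed Integer seed.
#' @return List of [roi_mask] objects, one per reader
#'   (`reader_id = "R1"..`).
#' @export
simulate_readers <- function(true_mask, n_readers, jitter_vox, seed) {
  stopifnot(n_readers >= 1, jitter_vox >= 0)
  label <- if (inherits(true_mask, "roi_mask")) true_mask$label else "ATT"
  m0 <- if (inherits(true_mask, "roi_mask")) true_mask$mask else true_mask
  with_seed_(as.integer(seed), {
    lapply(seq_len(n_readers), function(r) {
      j <- jitter_vox
      repeat {
        if (j == 0) { m <- m0; break }
        dx <- sample(-j:j, 1); dy <- sample(-j:j, 1)
        op <- sample(c(-1L, 0L, 1L), 1)
        m <- .morph_mask(.shift_mask(m0, dx, dy), op)
        if (any(m)) break
        warning("reader ", r, " jitter emptied the ROI; retrying with ",
                "jitter ", j - 1)
        j <- j - 1
      }
      roi_mask(m, label, reader_id = sprintf("R%d", r))
    })
  })
}
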