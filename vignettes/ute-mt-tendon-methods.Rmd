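---
title: "Two-pool UTE-MT modeling of tendon: model, fitting and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-pool UTE-MT modeling of tendon: model, fitting and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utemt)
```

## The measurement problem

Tendon is mostly collagen, and collagen protons relax far too fast
(T2 on the order of microseconds) to be imaged directly even with
ultrashort-echo-time (UTE) readouts. What can be measured is the *water*
signal after selectively saturating the macromolecular pool off-resonance:
saturation is transferred to the water pool by magnetization exchange, and
the amount of transfer depends on how large the macromolecular pool is.
Fitting a two-pool model to the saturated water signal across a grid of
saturation powers and frequency offsets yields the macromolecular proton
fraction (MMF) — an index of collagen content — and the macromolecular T2
(T2mm), without the orientation sensitivity (magic-angle effect) that
confounds relaxometry in highly ordered collagen.

This package implements that analysis end to end for a cohort comparison:
the forward signal model, T1 estimation, voxelwise and ROI-level fitting,
the group statistics, and a synthetic-cohort generator that stands in for
scan data.

## The forward model

The saturated, normalized steady-state signal for a condition with
continuous-wave-equivalent amplitude $\omega_1$ (rad/s) and offset $\Delta$
(Hz) is the standard two-pool steady-state expression

$$
\frac{S}{S_0} \;=\;
\frac{R_{1,mm}\frac{k_a}{R_{1,w}} + R_{rf,mm} + R_{1,mm} + k_b}
     {\frac{k_a}{R_{1,w}}\left(R_{1,mm} + R_{rf,mm}\right) +
      \left(1 + \left[\frac{\omega_1}{2\pi\Delta}\right]^2
      \frac{1}{R_{1,w} T_{2,w}}\right)\left(R_{rf,mm} + R_{1,mm} + k_b\right)}
$$

with

* $R_{rf,mm} = \pi \omega_1^2\, g(\Delta, T_{2,mm})$, the direct RF
  saturation rate of the macromolecular pool, using the Super-Lorentzian
  lineshape $g$ — the orientationally averaged absorption lineshape of
  semi-solid protons;
* $k_b$ the macromolecular-to-water exchange rate constant
  (`exch_rate`, s$^{-1}$) and $k_a = k_b f/(1-f)$ its water-to-macromolecular
  counterpart, where $f$ is the MMF;
* a Lorentzian direct-saturation term for the water pool governed by
  $T_{2,w}$;
* $R_{1,mm}$ fixed at 1 s$^{-1}$ — the universal qMT convention, since this
  rate is essentially unidentifiable from MT data;
* $R_{1,w}$ recovered from the separately measured observed rate
  $R_{1,obs} = 1/T_{1,obs}$ by inverting the slow eigenvalue of the coupled
  longitudinal system:
  $R_{1,w} = R_{1,obs} - k_a (R_{1,mm} - R_{1,obs}) / (R_{1,mm} - R_{1,obs} + k_b)$.

The Super-Lorentzian integral is evaluated by adaptive quadrature (absolute
tolerance $10^{-12}$) with the domain split at the magic angle
$\theta_m = \arccos(1/\sqrt 3)$, where the integrand has an integrable,
exponentially suppressed singularity. The lineshape diverges on resonance,
so offsets below 500 Hz are rejected; the smallest protocol offset is 2 kHz,
so this region is never needed in practice.

### Pulsed saturation as continuous-wave power

The acquisition saturates with a train of Fermi pulses (one per
preparation of 9 UTE spokes), not continuous irradiation. Following the
modified-rectangular-pulse treatment, each pulse train is reduced to the
continuous-wave amplitude $\omega_{1,CWPE}$ whose mean-square power over one
preparation period equals that of the train. The Fermi envelope is
parameterized with a flat top of half-width $0.35\tau$ and a transition
width of $\tau/60$ for a pulse of duration $\tau$; its area and power shape
factors are computed by quadrature once and cached (they are
scale-invariant). The degrees-to-rad/s conversion of the nominal pulse
power happens in exactly one place, `cw_power_equivalent()`. Defaults are an
8 ms pulse in a 40.6 ms preparation period; `mt_protocol()` exposes both.

A full Bloch–McConnell time-domain simulation of the pulse train is out of
scope; the CW-power-equivalent approximation is the regime this protocol
(long pulses, many spokes per preparation) was designed for.

## T1 estimation

The observed T1 is a required input of the MT fit. It is estimated from a
variable-TR (VTR) series by bounded Levenberg–Marquardt least squares on

$$S(TR) = A\,(1 - e^{-TR/T_1}) + C, \qquad T_1 \in [100, 5000]\ \mathrm{ms}.$$

With the study's three TRs (20/80/150 ms), three points determine the three
parameters exactly in the noiseless case; the suite verifies recovery to
numerical precision. Because all TRs sit well below tendon T1
($\approx$ 700–850 ms), the exponential is nearly linear over the sampled
range and the fit is poorly conditioned: at image SNR 50, single-ROI T1
errors of 10–30% occur. This is a property of the three-TR design itself,
not of the optimizer, and it propagates only weakly into MMF.

The dual-TR AFI pair gives the actual excitation angle through
$\cos\alpha = (rn-1)/(n-r)$, $r = S_2/S_1$, $n = TR_2/TR_1$. The
saturation-recovery fit above is amplitude-normalized, so the correction
affects the interpretation of $A$, not the T1 estimate; the pipeline
records the recovered angle per ROI as a quality check.

## Fitting choices

`fit_two_pool()` minimizes squared residuals over
(MMF, T2mm, exchange rate, water T2, amplitude) with bounds
MMF $\in [0.01, 0.9]$, T2mm $\in [1, 50]$ µs, exchange $\in [1, 100]$
s$^{-1}$, water T2 $\in [0.1, 100]$ ms, using `minpack.lm`'s bounded
Levenberg–Marquardt (ftol = ptol = $10^{-10}$, 500 iterations max).

* **Multi-start.** Three deterministic starting points bracket the
  published tendon range: MMF {0.08, 0.17, 0.30} paired with T2mm
  {5, 7.5, 12} µs and water-T2 {1.5, 5, 15} ms, exchange always 30
  s$^{-1}$. The lowest-residual solution wins, so identical inputs give
  bit-identical results. The water-T2 values are spread because a common
  start for that parameter can strand the optimizer in a local minimum
  when the true water T2 is large.
* **Amplitude.** $S_0$ is a free parameter rather than a division by a
  reference acquisition — the protocol contains no saturation-free volume,
  and an absolute-scale fit avoids consecrating any one condition as
  noise-free truth.
* **Water T2.** Fitted by default; `fit_t2w = FALSE` fixes it (2 ms
  default), for protocols too sparse to constrain it.
* **ROI versus voxel.** ROI-level analysis fits the ROI-averaged signal
  per condition (matching an analysis of mean saturation curves);
  `fit_voxelwise()` fits each voxel with its own T1 and assembles maps
  with a per-voxel residual-norm quality map, flagging failed voxels and
  warning if more than half fail.

## Image conditioning and ROI statistics

Every volume is smoothed in-plane before fitting with a 3×3 Gaussian
kernel. The kernel width is not dictated by the window size; $\sigma$ = 0.8
px makes the 3×3 truncation mild, and the truncated kernel is renormalized
to unit sum. Boundary handling is edge replication so structures near the
volume border are not darkened. Whether to smooth per-slice or in 3-D is an
open choice; "3×3 sub-window" reads as 2-D, so smoothing is per slice.

ROI summaries use the arithmetic mean and the sample (n−1) SD. In the
subject pipeline each reader's mask is eroded in-plane by one voxel before
averaging (`erode_margin = 1`): boundary voxels mix tendon and background
signal after smoothing, and excluding them is the usual convention when
measuring small structures. Setting `erode_margin = 0` measures the full
contour.

## Cohort statistics

* **Group comparison.** Two-sided Wilcoxon rank-sum per tendon and
  parameter, appropriate for the unequal cohort sizes (26 young, 22
  elderly). The exact null distribution is used when the pooled sample is
  at most 20 without ties; otherwise the normal approximation with tie and
  continuity correction. α = 0.05, and no multiple-testing correction is
  applied (the original analysis applied none); reports flag this.
* **Percent differences** are always relative to the young-cohort mean.
* **Reader agreement.** ICC(2,1): two-way random effects, absolute
  agreement, single rater — the standard form when readers are
  interchangeable and each reads every case. It is computed from the
  mean-squares decomposition across all subject-tendon units pooled over
  cohorts (per parameter); pooling is a choice, and the ratings matrix
  interface accepts any stratification.
* **Reader aggregation.** Reader measurements are averaged within subject
  and tendon before any cohort statistic.

## What the synthetic cohort emulates

`cohort_spec()` defaults encode the study conditions: 26 young and 22
elderly subjects; per-(cohort, tendon) normal distributions for T1, MMF and
T2mm at the reference means and SDs (`tendon_reference_table()`), truncated
at physical bounds; three readers; 1-voxel ROI jitter; image SNR 50.
Parameters the reference table does not cover needed one-time choices:
exchange rate 30 ± 5 s$^{-1}$ and water T2 2 ± 0.3 ms, mid-range tendon
values; ATT and PTT draws correlate at 0.5 within subject, a conservative
middle ground for the rank test between independence and the strong
within-person correlation plausible for neighboring tendons.

Each subject becomes a 64×64×4 phantom with two elliptical tendon
cross-sections (about 220 and 300 voxels per slice) in a muscle-like
background (MMF 8%, T1 1400 ms, water T2 25 ms). Every MT condition volume
is filled from the forward model, the VTR volumes from the
saturation-recovery equation and the AFI pair from the dual-TR steady
state; Rician noise is then applied, with the SNR referenced to the
brightest tendon signal of each series separately, since each series
carries its own receiver scaling on a scanner. Readers are simulated by
translating the true mask by up to the jitter and randomly dilating or
eroding it by one voxel. The phantom geometry, SNR and jitter defaults were
calibrated together so that the simulated study sits in the same operating
regime as the measured one — reader ICC above 0.98 and a significant PTT
MMF contrast — which is exactly what these free parameters control.

What the generator does **not** emulate: real anatomy and partial-volume
structure beyond a smoothed ellipse edge, inter-series motion and
registration error (registration is accepted as an upstream step; the
pipeline only asserts shape agreement), B0/B1 field maps beyond a scalar B1
factor, fat signal, and k-space/trajectory effects. Passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions — an inverse-crime setting — plus robustness to Rician noise
and reader variability, not robustness to everything real data contains.

## Numerical and degenerate-input behavior

* Lineshape quadrature: adaptive, split at the magic angle, absolute
  tolerance $10^{-12}$; verified against an independent implementation at
  $10^{-10}$.
* The pole of $f/(1-f)$ at the MMF bounds is guarded by clamping $f$ to
  $[10^{-9}, 1-10^{-9}]$ inside the model kernel.
* Flat VTR series (zero amplitude) return `converged = FALSE` rather than
  an arbitrary T1; unsaturated MT data drive MMF to its lower bound and the
  result names the bound in `at_bound`.
* AFI signal ratios outside $(TR_1/TR_2, 1)$ are non-physical and error;
  a ratio of exactly 1 returns the zero-flip limit.
* All randomness (noise, cohort draws, reader placement) is seeded through
  one local-RNG helper that restores the caller's RNG state, so package
  calls never perturb a session's random stream.

## Problem sizes

The shipped analyses use the full 48-subject cohort (about a minute for the
imaging pipeline on one core). The test suite exercises the same paths at
reduced size — cohorts of 4–16 subjects, single- or two-slice phantoms, 25
random draws for noiseless recovery, 100 replicates for noisy recovery,
200 parameter-level cohort replicates — sizes chosen so the full suite runs
in about a minute while keeping every statistical check comfortably
powered.

## Known limitations

* The three-TR VTR design conditions T1 weakly (see above); cohort-level
  T1 comparisons inherit that variance.
* ROI-mean fitting assumes the ROI is homogeneous; strong within-ROI
  gradients would bias the nonlinear fit relative to averaging voxelwise
  fits. Both routes are provided.
* The exchange rate is estimated but weakly identified on a 3×5 grid;
  its generating distribution in the simulator is a stated assumption, not
  a reproduced measurement.
* DICOM reading is not implemented; the I/O layer speaks NIfTI with JSON
  sidecars for condition metadata.
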