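# utemt

Quantitative magnetization-transfer (qMT) analysis for ultrashort echo
time (UTE) MRI of tendon, built around the question it was designed to
answer: *does the collagen proton fraction of human leg tendons decrease
with age, and can three independent readers agree on it?*

Tendon collagen protons have microsecond T2 and cannot be imaged directly.
Saturating them off-resonance and modeling the transfer of that saturation
to the water pool yields the **macromolecular proton fraction (MMF)** — a
surrogate for collagen content — and the **macromolecular T2 (T2mm)**,
largely free of the magic-angle orientation sensitivity that confounds
tendon relaxometry. The package implements:

- the two-pool continuous-wave-power-equivalent steady-state signal model
  with a Super-Lorentzian macromolecular lineshape,
  $R_{rf,mm} = \pi\,\omega_{1,CWPE}^2\, g(\Delta, T_{2mm})$, water-pool
  direct saturation, exchange $k_b$ (with $k_a = k_b f/(1-f)$) and the
  observed-R1 correction with $R_{1,mm}$ fixed at 1 s⁻¹;
- the CW power equivalent of a pulsed Fermi saturation train
  (mean-square-power matching over the preparation period);
- variable-TR T1 fitting, $S(TR) = A(1 - e^{-TR/T_1}) + C$, with the
  dual-TR AFI actual-flip-angle relation
  $\cos\alpha = (rn - 1)/(n - r)$;
- bounded, deterministic multi-start Levenberg–Marquardt fitting of
  (MMF, T2mm, exchange, water T2, amplitude), per ROI or per voxel;
- 3×3 Gaussian in-plane pre-smoothing and ROI statistics;
- cohort statistics: two-sided Wilcoxon rank-sum tests, elderly-vs-young
  percent differences, and inter-reader ICC(2,1);
- a synthetic-cohort generator (tendon phantoms, Rician noise, simulated
  reader ROI placement) so the whole analysis runs without scan data.

## Worked example

Simulate a posterior tibialis tendon ROI at the young-cohort parameters
(MMF 21.3 %, T2mm 7.3 µs, T1 735 ms), add Rician noise at SNR 100, and fit:

```r
library(utemt)
protocol <- default_mt_protocol()   # 500/1000/1500 deg x 2/5/10/20/50 kHz
truth <- tissue_params(mmf = 0.213, t2_mm_us = 7.3, t2_w_ms = 2,
                       t1_obs_ms = 735, exch_rate = 30)
sat <- add_rician_noise(forward_signal(truth, protocol), snr = 100, seed = 21)
sat
#> Normalized MT saturation data (S/S0):
#>          offset_khz
#> power_deg      2      5     10     20     50
#>      500  0.3875 0.5506 0.7025 0.9091 0.9920
#>      1000 0.1667 0.3171 0.4204 0.7009 0.9916
#>      1500 0.1119 0.2035 0.2955 0.5632 0.9832

fit_two_pool(sat, t1_obs_ms = 735)
#> Fit (converged, 7 iterations, SSR 0.00096)
#> Two-pool tissue parameters:
#>   MMF 24.0%  T2mm 7.45 us  T2w 2.39 ms  T1obs 735 ms  k 22.0 /s  S0 0.999
```

Signal drops with saturation power and recovers with offset; the fit
returns MMF within a few points of truth for a single noisy ROI grid
(averaging over readers and subjects tightens this). The T1 input comes
from the variable-TR fit:

```r
trs <- c(20, 80, 150)
fit_t1_vtr(1 - exp(-trs / 735), trs)$t1_ms
#> [1] 735
```

## The cohort analysis

The `analysis/` scripts run the full synthetic study and write their
tables under `results/`:

| stage | what it does |
| --- | --- |
| `01_simulate_cohort.R` | draws 26 young + 22 elderly subjects from the reference tendon distributions; writes ground truth and one example subject as NIfTI + JSON sidecars |
| `02_fit_cohort.R` | generates each subject's phantom and runs smoothing, three jittered readers, T1 and MT fits per ROI |
| `03_cohort_statistics.R` | reader-averaged cohort summaries, percent differences with rank-sum p-values, ICC(2,1) |
| `04_replicate_comparison.R` | 200 replicate cohorts at the generating distributions (no imaging): sampling behaviour of the age contrast |
| `05_figures.R` | saturation-curve fits, a voxelwise MMF map, the cohort boxplot |

On the shipped seed the pipeline finds what the study design expects: MMF
significantly lower in the elderly cohort at the PTT (−16.3 %, p = 0.008),
no significant T1 or T2mm differences, and inter-reader ICC of 0.98–0.99.

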