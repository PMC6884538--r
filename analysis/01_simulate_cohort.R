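#!/usr/bin/env Rscript
# Stage 1: draw the synthetic study cohort (26 young, 22 elderly subjects,
# ATT and PTT per subject) from the reference tendon distributions and
# write the ground truth; also write one example subject's image volumes
# so the on-disk format can be inspected.

library(utemt)

seed <- 11L
spec <- cohort_spec(seed = seed)
dir.create("results", showWarnings = FALSE)

truth <- sample_cohort(spec)
write_cohort_table(truth, "results/cohort_truth.csv", seed = seed,
                   config = spec[c("n_young", "n_elderly", "snr",
                                   "n_readers", "reader_jitter_vox")])
message(sprintf("Sampled %d subjects (%d young / %d elderly).",
                length(unique(truth$subject_id)), spec$n_young,
                spec$n_elderly))
for (co in c("young", "elderly")) {
  for (td in c("ATT", "PTT")) {
    v <- 100 * truth$mmf_frac[truth$cohort == co & truth$tendon == td]
    message(sprintf("  %s %s MMF: %.1f +/- %.1f %%", co, td, mean(v), sd(v)))
  }
}

# one example subject written as NIfTI volumes + JSON sidecars
sub <- truth[truth$subject_id == "Y01", ]
par_of <- function(td) {
  r <- sub[sub$tendon == td, ]
  tissue_params(r$mmf_frac, r$t2mm_us, r$t2w_ms, r$t1_ms, r$exch_rate)
}
ds <- generate_subject_dataset(par_of("ATT"), par_of("PTT"),
                               default_mt_protocol(), snr = spec$snr,
                               seed = seed + 1001L)
write_subject_dataset(ds, "results/example_subject", "Y01")
write_mt_protocol(default_mt_protocol(), "results/protocol.yaml")
message("Wrote results/cohort_truth.csv and results/example_subject/.")
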