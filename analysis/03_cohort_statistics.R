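#!/usr/bin/env Rscript
# Stage 3: the cohort statistics -- reader-averaged per-subject values,
# cohort mean +/- SD per tendon and parameter, elderly-vs-young percent
# differences with two-sided Wilcoxon rank-sum p-values, and inter-reader
# ICC(2,1) per parameter.

library(utemt)

est <- read_cohort_table("results/cohort_estimates.csv")
s <- summarize_cohort(est)

write.csv(s$summary, "results/table_summary.csv", row.names = FALSE)
write.csv(s$differences, "results/table_differences.csv", row.names = FALSE)
write.csv(s$icc, "results/table_icc.csv", row.names = FALSE)
write.csv(s$per_subject, "results/per_subject.csv", row.names = FALSE)

message("Cohort summary (mean +/- SD):")
for (i in seq_len(nrow(s$summary))) {
  r <- s$summary[i, ]
  message(sprintf("  %-7s %s %-9s %8.1f +/- %.1f  (n=%d)",
                  r$cohort, r$tendon, r$parameter, r$mean, r$sd, r$n))
}
message("Elderly vs young differences:")
for (i in seq_len(nrow(s$differences))) {
  r <- s$differences[i, ]
  message(sprintf("  %s %-9s %+6.1f%%  (p = %.3g%s)", r$tendon, r$parameter,
                  r$percent_difference, r$p_value,
                  if (r$significant) ", significant" else ""))
}
message("Inter-reader agreement:")
for (i in seq_len(nrow(s$icc))) {
  r <- s$icc[i, ]
  message(sprintf("  %-9s ICC(2,1) = %.3f over %d readers", r$parameter,
                  r$icc, r$n_readers))
}
message("Wrote results/table_{summary,differences,icc}.csv.")
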