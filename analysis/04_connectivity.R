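#!/usr/bin/env Rscript
# Monosynaptic-tracing connectivity of the simulated brains: starter
# interpolation, per-brain connectivity ratios, the group-by-region summary
# table and TBI-vs-matching-control comparisons.
# Reads results/data/tracing_*.csv; writes results/tracing/*.csv.

suppressPackageStartupMessages(library(contraplast))

tabs <- read_tracing_tables("results/data/tracing_counts.csv",
                            "results/data/tracing_starters.csv")
out <- "results/tracing"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

res <- build_connectivity_table(
  tabs$counts, tabs$starters,
  comparisons = list(c("tbi_7d", "control_7d"), c("tbi_42d", "control_42d")))
write.csv(res$ratios, file.path(out, "ratios_per_brain.csv"), row.names = FALSE)
write.csv(res$table, file.path(out, "connectivity_table.csv"), row.names = FALSE)
write.csv(res$comparisons, file.path(out, "group_comparisons.csv"),
          row.names = FALSE)

if (length(res$excluded_brains) > 0) {
  message("excluded for zero starters: ",
          paste(res$excluded_brains, collapse = ", "))
}
ss <- res$table[res$table$region == "somatosensory", ]
for (i in seq_len(nrow(ss))) {
  message(sprintf("somatosensory %-12s ratio %.2f +/- %.2f (n=%d)",
                  ss$group[i], ss$mean[i], ss$sem[i], ss$n[i]))
}
sig <- res$comparisons[!is.na(res$comparisons$p_value) &
                         res$comparisons$p_value < 0.05, ]
message(sprintf("%d of %d region comparisons significant at p < 0.05",
                nrow(sig), sum(!is.na(res$comparisons$p_value))))
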