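#!/usr/bin/env Rscript
# Stage 3: classify the DRGs into the nine feature/direction clusters,
# validate the partition algebra and summarize fold changes per cluster.

suppressPackageStartupMessages(library(epidrg))

drgs <- read_drg_table("results/bundle/drgs.tsv")
profiles <- read_tsv("results/profiles.tsv")

memberships <- classify(drgs, profiles)
violations <- validate_partition(memberships)
stopifnot(nrow(violations) == 0L)
write_tsv(memberships, "results/clusters.tsv")

fc <- fold_change_summary(memberships, drgs)
write_tsv(fc, "results/fold_change_summary.tsv")

message("cluster sizes and mean |fold change|:")
for (i in seq_len(nrow(fc))) {
  message(sprintf("  %-4s n = %5d  (%5.1f%% of parent)  mean |FC| = %6.2f",
                  fc$cluster[i], fc$n_genes[i], fc$percent_of_parent[i],
                  fc$mean_abs_fold_change[i]))
}
up <- fc$mean_abs_fold_change[fc$cluster %in% c("DU", "EU", "NEU")]
down <- fc$mean_abs_fold_change[fc$cluster %in% c("DD", "ED", "NED")]
message(sprintf("up-regulated clusters average |FC| %.2f vs %.2f for down-regulated ones",
                mean(up), mean(down)))
message("partition algebra: no violations")
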