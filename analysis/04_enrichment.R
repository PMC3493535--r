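#!/usr/bin/env Rscript
# Stage 4: enrichment statistics.
#
# Monte Carlo z-scores compare the feature content of the DRG set with
# size-matched random gene lists drawn from the eligible pool (all
# non-TE, non-pseudogene models; DRGs retained). The closed-form
# binomial z is reported alongside as a cross-check. GO-term enrichment
# per leaf cluster uses the one-sided Fisher exact test with
# Benjamini-Yekutieli correction and a minimum of five mapped entries.

suppressPackageStartupMessages(library(epidrg))

seed <- 2012L
genes <- read_gene_models("results/bundle/genes.tsv", "tsv")
go <- read_go_annotations("results/bundle/go.tsv")
profiles <- read_tsv("results/profiles.tsv")
memberships <- read_tsv("results/clusters.tsv")

pool <- eligible_pool(genes)
drg_ids <- cluster_members(memberships, "D")
feature_sets <- list(
  genic = profiles$gene_id[profiles$genic_read_count >= 1],
  promoter = profiles$gene_id[profiles$promoter_read_count >= 1],
  mirna = profiles$gene_id[profiles$mirna_count >= 1],
  chromdb = profiles$gene_id[profiles$is_chromdb])

ez <- do.call(rbind, lapply(names(feature_sets), function(f) {
  rbind(mc_enrichment_z(drg_ids, feature_sets[[f]], pool,
                        n_draws = 1000, seed = seed, feature = f),
        binomial_z(drg_ids, feature_sets[[f]], pool, feature = f))
}))
write_tsv(ez, "results/enrichment_z.tsv")
message("feature enrichment of the DRG set vs random gene lists:")
mc <- ez[ez$method == "monte_carlo", ]
for (i in seq_len(nrow(mc))) {
  message(sprintf("  %-9s observed %5d  bg %7.1f +/- %5.1f  z = %6.2f",
                  mc$feature[i], mc$observed[i], mc$bg_mean[i],
                  mc$bg_sd[i], mc$z[i]))
}

for (lab in c("EU", "ED", "NEU", "NED")) {
  q <- intersect(cluster_members(memberships, lab), pool)
  res <- fisher_term_enrichment(q, go, pool, min_mapped = 5,
                                alpha = 0.05)
  write_tsv(res, paste0("results/go_enrichment_", lab, ".tsv"))
  message(sprintf("GO enrichment %s: %d terms tested, %d enriched (BY < 0.05)",
                  lab, nrow(res), sum(res$enriched)))
}
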