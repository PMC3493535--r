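#!/usr/bin/env Rscript
# Stage 2: map methylation reads onto genic and promoter regions and
# assemble the per-gene feature profiles.
#
# Genic assignment uses the 50-base minimum-overlap rule; promoter
# assignment counts any read touching the 1 kb window upstream of the
# TSS. Descriptive summaries echo the study's reporting: feature
# prevalence among DRGs, mean gene lengths of methylated vs unmethylated
# DRGs, co-occurrence of features and multiplicity histograms.

suppressPackageStartupMessages(library(epidrg))

genes <- read_gene_models("results/bundle/genes.tsv", "tsv")
reads <- read_intervals_bed("results/bundle/reads.bed")
drgs <- read_drg_table("results/bundle/drgs.tsv")
mirna <- read_pair_table("results/bundle/mirna.tsv", "mirna_target")
chromdb <- read_pair_table("results/bundle/chromdb.tsv", "chromdb")

genic <- map_reads_to_genic(genes, reads, min_overlap = 50)
windows <- promoter_windows(genes, upstream = 1000)
prom <- map_reads_to_promoters(windows, reads, min_overlap = 1)
profiles <- build_feature_profiles(genes, genic, prom, mirna, chromdb,
                                   reads)
write_tsv(profiles[, !vapply(profiles, is.list, TRUE)],
          "results/profiles.tsv")

drg_ids <- unique(drgs$gene_id)
dp <- profiles[profiles$gene_id %in% drg_ids, ]
n_genic <- sum(dp$genic_read_count >= 1)
message(sprintf("DRGs with genic methylation reads: %d (%.1f%%)",
                n_genic, pct(n_genic, length(drg_ids))))
message(sprintf("  of these with >1 read: %d (%.1f%%)",
                sum(dp$genic_read_count > 1),
                pct(sum(dp$genic_read_count > 1), n_genic)))
message(sprintf("DRGs with promoter methylation reads: %d (%.1f%%)",
                sum(dp$promoter_read_count >= 1),
                pct(sum(dp$promoter_read_count >= 1), length(drg_ids))))
message(sprintf("DRGs targeted by miRNAs: %d (%.1f%%)",
                sum(dp$mirna_count >= 1),
                pct(sum(dp$mirna_count >= 1), length(drg_ids))))

meth <- dp$gene_id[dp$genic_read_count >= 1]
ls <- length_summary(genes, list(
  all_genes = genes$gene_id, drg = drg_ids, drg_methylated = meth,
  drg_unmethylated = setdiff(drg_ids, meth)))
write_tsv(ls, "results/length_summary.tsv")
message(sprintf("mean gene length, methylated vs unmethylated DRGs: %.0f vs %.0f",
                ls$mean_length[ls$partition == "drg_methylated"],
                ls$mean_length[ls$partition == "drg_unmethylated"]))

co <- feature_cooccurrence(profiles, universe = drg_ids)
write_tsv(data.frame(bucket = c(paste0("only_", names(co$unique)),
                                names(co$pairwise),
                                "genic_promoter_mirna", "any", "none"),
                     n_genes = c(co$unique, co$pairwise,
                                 co$triple_genic_promoter_mirna,
                                 co$any, co$none)),
          "results/cooccurrence.tsv")

hist_tabs <- lapply(c("genic", "promoter", "mirna"), function(f) {
  h <- multiplicity_histogram(dp, f)
  if (nrow(h)) data.frame(feature = f, h) else NULL
})
write_tsv(do.call(rbind, hist_tabs), "results/multiplicity.tsv")
message("profiles and summaries written under results/")
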