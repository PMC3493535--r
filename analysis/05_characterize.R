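#!/usr/bin/env Rscript
# Stage 5: cluster characterization.
#
# TF-family, Pfam-family and pathway distributions across the nine
# clusters; Pfam G-statistics for E vs NE and DU vs DD; within-cluster
# PPI degree summaries under the combined-score filter; four-set
# overlaps of the leaf clusters' annotation repertoires; and the
# consolidated leaf-cluster summary table.

suppressPackageStartupMessages(library(epidrg))

genes <- read_gene_models("results/bundle/genes.tsv", "tsv")
drgs <- read_drg_table("results/bundle/drgs.tsv")
profiles <- read_tsv("results/profiles.tsv")
memberships <- read_tsv("results/clusters.tsv")
tf <- read_pair_table("results/bundle/tf.tsv", "tf_family")
pfam <- read_pair_table("results/bundle/pfam.tsv", "pfam")
pathway <- read_pair_table("results/bundle/pathway.tsv", "pathway")
ppi <- read_pair_table("results/bundle/ppi.tsv", "ppi_edge")

for (x in list(list(tf, "tf"), list(pfam, "pfam"),
               list(pathway, "pathway"))) {
  totals <- table(x[[1]]$subject_id)
  fd <- family_distribution(memberships, x[[1]],
                            genome_totals = totals)
  write_tsv(fd, paste0("results/", x[[2]], "_distribution.tsv"))
}
n_tf_drg <- sum(cluster_members(memberships, "D") %in% tf$gene_id)
message(sprintf("TF genes among DRGs: %d (%.2f%%)", n_tf_drg,
                pct(n_tf_drg, length(cluster_members(memberships, "D")),
                    2)))

# Pfam-bearing share: E vs NE and DU vs DD with the G statistic
g_of <- function(a_lab, b_lab) {
  a <- cluster_members(memberships, a_lab)
  b <- cluster_members(memberships, b_lab)
  tab <- matrix(c(sum(a %in% pfam$gene_id), sum(!(a %in% pfam$gene_id)),
                  sum(b %in% pfam$gene_id), sum(!(b %in% pfam$gene_id))),
                2, 2, byrow = TRUE)
  g <- g_statistic(tab)
  message(sprintf("  %s %.1f%% vs %s %.1f%%: G = %.2f (p = %.3g)",
                  a_lab, pct(tab[1, 1], sum(tab[1, ])),
                  b_lab, pct(tab[2, 1], sum(tab[2, ])), g$g, g$p))
  invisible(g)
}
message("Pfam-bearing gene shares:")
g_of("E", "NE")
g_of("DU", "DD")

leafs <- c("EU", "ED", "NEU", "NED")
message("within-cluster PPIs (combined score >= 0.04):")
ppi_rows <- do.call(rbind, lapply(leafs, function(lab) {
  s <- ppi_degree_summary(cluster_members(memberships, lab), ppi,
                          score_threshold = 0.04,
                          score_direction = "ge")
  message(sprintf("  %-4s genes with PPIs: %4d (%4.1f%%), %.2f PPIs per gene with >= 1",
                  lab, s$n_genes_with_edge,
                  pct(s$n_genes_with_edge, s$n_genes),
                  s$mean_degree_positive))
  data.frame(cluster = lab, n_genes = s$n_genes,
             n_genes_with_edge = s$n_genes_with_edge,
             total_edges_within = s$total_edges_within,
             mean_degree_all = round(s$mean_degree_all, 3),
             mean_degree_positive = round(s$mean_degree_positive, 3),
             top_genes = paste(s$top_genes$gene_id, collapse = ","))
}))
write_tsv(ppi_rows, "results/ppi_summary.tsv")

leaf_sets <- function(pairs) {
  lapply(setNames(leafs, leafs), function(lab)
    unique(pairs$subject_id[pairs$gene_id %in%
                              cluster_members(memberships, lab)]))
}
go_sets <- lapply(setNames(leafs, leafs), function(lab) {
  res <- read_tsv(paste0("results/go_enrichment_", lab, ".tsv"))
  res$term_id[res$enriched]
})
kinds <- list(go = go_sets, tf = leaf_sets(tf), pfam = leaf_sets(pfam),
              pathway = leaf_sets(pathway))
ov_tab <- do.call(rbind, lapply(names(kinds), function(kind) {
  ov <- four_set_overlap(kinds[[kind]])
  data.frame(kind = kind, region = names(ov$regions),
             count = as.integer(ov$regions))
}))
write_tsv(ov_tab, "results/overlap_counts.tsv")

summary_tab <- cluster_summary_table(
  memberships, drgs, profiles, ppi, tf_pairs = tf, pfam_pairs = pfam,
  go_sets = go_sets, pathway_sets = kinds$pathway,
  score_threshold = 0.04, score_direction = "ge")
write_tsv(summary_tab, "results/cluster_summary.tsv")
message("leaf-cluster summary written to results/cluster_summary.tsv")
print(summary_tab[, c("cluster", "n_genes", "mean_abs_fold_change",
                      "pct_genic", "pct_promoter", "pct_mirna",
                      "pct_with_ppi", "pct_tf", "pct_pfam")])
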