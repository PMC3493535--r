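# Per-cluster descriptive analytics: family distributions (TF, Pfam,
# pathway), PPI degree summaries under a score filter, four-set overlap
# (Venn) counts and the consolidated leaf-cluster summary table.

LEAF_CLUSTERS <- c("EU", "ED", "NEU", "NED")

#' Family membership counts across the nine clusters
#'
#' For each family (TF family, Pfam family or pathway), the number of
#' member genes in each of the nine clusters, its genome-wide total and
#' the percentage of the family that is drought responsive
#' (`100 * D count / genome total`, 2 decimals).
#'
#' @param memberships output of [classify()].
#' @param pairs pair table of a single kind (`tf_family`, `pfam` or
#'   `pathway`).
#' @param genome_totals named integer vector, family -> genome-wide gene
#'   count; families missing from it get `NA` totals with a warning.
#' @return data.frame, one row per family present among the DRGs, sorted
#'   by descending D count.
#' @export
family_distribution <- function(memberships, pairs, genome_totals = NULL) {
  if (length(unique(pairs$kind)) > 1L) {
    stop_input("pairs must be of a single kind")
  }
  sets <- setNames(lapply(CLUSTER_LABELS, cluster_members,
                          memberships = memberships), CLUSTER_LABELS)
  in_d <- pairs[pairs$gene_id %in% sets$D, , drop = FALSE]
  fams <- sort(unique(in_d$subject_id))
  genes_by_fam <- split(in_d$gene_id, in_d$subject_id)[fams]
  counts <- vapply(CLUSTER_LABELS, function(lab) {
    vapply(genes_by_fam, function(g) sum(g %in% sets[[lab]]), 0L)
  }, integer(length(fams)))
  counts <- matrix(counts, nrow = length(fams),
                   dimnames = list(fams, CLUSTER_LABELS))
  total <- rep(NA_integer_, length(fams))
  if (!is.null(genome_totals)) {
    total <- as.integer(genome_totals[fams])
    if (anyNA(total)) {
      warning(sum(is.na(total)),
              " family(ies) missing from genome_totals; total unknown",
              call. = FALSE)
    }
  }
  out <- data.frame(family_id = fams,
                    kind = if (nrow(pairs)) pairs$kind[1L] else
                      character(0),
                    counts, total_in_genome = total,
                    percent_drg_of_family = pct(counts[, "D"], total, 2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$D, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Within-cluster PPI degree summary
#'
#' Keeps only edges whose two endpoints both lie in `cluster_genes` and
#' whose combined score passes the threshold; `score_direction` must be
#' given explicitly (`"ge"`: keep score >= threshold, i.e. confidence
#' scores; `"le"`: keep score <= threshold, i.e. p-value-like scores).
#' Degrees count within-cluster incident edges only.
#'
#' @param cluster_genes gene-id set of one cluster.
#' @param edges PPI pair table (`kind = "ppi_edge"`, canonical undirected
#'   form from [read_pair_table()]).
#' @param score_threshold numeric threshold on the combined score.
#' @param score_direction `"ge"` or `"le"` (no default).
#' @param k number of top-degree genes to report (ties broken by gene id
#'   ascending).
#' @return list: `n_genes`, `n_genes_with_edge`, `total_edges_within`,
#'   `mean_degree_all`, `mean_degree_positive`, `top_genes` (data.frame
#'   `gene_id`, `degree`).
#' @export
ppi_degree_summary <- function(cluster_genes, edges, score_threshold,
                               score_direction = c("ge", "le"), k = 10) {
  score_direction <- match.arg(score_direction)
  if (k < 1) stop_input("k must be >= 1")
  pass <- if (score_direction == "ge") edges$score >= score_threshold else
    edges$score <= score_threshold
  keep <- pass & edges$subject_id %in% cluster_genes &
    edges$gene_id %in% cluster_genes
  sub <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    sub[c("subject_id", "gene_id")], directed = FALSE,
    vertices = data.frame(name = sort(unique(cluster_genes)))
  )
  deg <- igraph::degree(g)
  pos <- deg[deg > 0]
  ord <- order(-deg, names(deg))
  top <- data.frame(gene_id = names(deg)[ord], degree = as.integer(deg[ord]),
                    stringsAsFactors = FALSE)[seq_len(min(k, length(deg))), ,
                                              drop = FALSE]
  rownames(top) <- NULL
  list(n_genes = length(deg),
       n_genes_with_edge = length(pos),
       total_edges_within = nrow(sub),
       mean_degree_all = if (length(deg)) mean(deg) else NA_real_,
       mean_degree_positive = if (length(pos)) mean(pos) else NA_real_,
       top_genes = top)
}

#' Four-set overlap (Venn) region counts
#'
#' Counts of the 15 exclusive regions of a four-set Venn diagram; region
#' names join the member set names with `"&"`. The region counts sum to
#' the size of the union.
#'
#' @param sets named list of exactly 4 character vectors with distinct
#'   names.
#' @return list: `set_names`, `regions` (named integer vector of length
#'   15).
#' @export
four_set_overlap <- function(sets) {
  if (length(sets) != 4L || is.null(names(sets)) ||
      anyDuplicated(names(sets)) || any(names(sets) == "")) {
    stop_input("sets must be a named list of exactly 4 distinct names")
  }
  nm <- names(sets)
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets, use.names = FALSE))
  memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
  memb <- matrix(memb, nrow = length(u), dimnames = list(NULL, nm))
  masks <- expand.grid(rep(list(c(FALSE, TRUE)), 4))[-1L, , drop = FALSE]
  region_name <- apply(masks, 1, function(b) paste(nm[as.logical(b)],
                                                   collapse = "&"))
  counts <- apply(masks, 1, function(b) {
    if (!length(u)) return(0L)
    sum(colSums(t(memb) == as.logical(b)) == 4L)
  })
  list(set_names = nm, regions = setNames(as.integer(counts), region_name))
}

#' Consolidated leaf-cluster summary table
#'
#' One row per leaf cluster (EU, ED, NEU, NED) collecting: mean absolute
#' fold change; counts and percentages of genes with promoter methylation
#' reads, genic methylation reads, miRNA targets, chromdb membership;
#' genes with at least one within-cluster PPI; TF genes; Pfam-bearing
#' genes; and the number of GO terms / pathways unique to the cluster
#' among the four leaves ([four_set_overlap()] singleton regions).
#' Percentages are over the cluster size, 1 decimal; counts are always
#' emitted alongside.
#'
#' @param memberships output of [classify()].
#' @param drgs DRG table.
#' @param profiles feature profiles.
#' @param ppi_edges PPI pair table.
#' @param tf_pairs,pfam_pairs pair tables (`tf_family`, `pfam`).
#' @param go_sets named list (EU/ED/NEU/NED) of significant GO term ids
#'   per leaf cluster, or `NULL`.
#' @param pathway_sets named list of pathway ids per leaf cluster, or
#'   `NULL`.
#' @param score_threshold,score_direction PPI score filter (see
#'   [ppi_degree_summary()]).
#' @param reduce per-gene fold-change reduction.
#' @return data.frame, one row per leaf cluster.
#' @export
cluster_summary_table <- function(memberships, drgs, profiles, ppi_edges,
                                  tf_pairs = NULL, pfam_pairs = NULL,
                                  go_sets = NULL, pathway_sets = NULL,
                                  score_threshold = 0.04,
                                  score_direction = c("ge", "le"),
                                  reduce = c("max", "mean")) {
  score_direction <- match.arg(score_direction)
  fc <- gene_fold_change(drgs, reduce)
  unique_region <- function(sets_list) {
    if (is.null(sets_list)) return(setNames(rep(NA_integer_, 4),
                                            LEAF_CLUSTERS))
    miss <- setdiff(LEAF_CLUSTERS, names(sets_list))
    if (length(miss)) stop_input("missing leaf set(s): ",
                                 paste(miss, collapse = ", "))
    ov <- four_set_overlap(sets_list[LEAF_CLUSTERS])
    setNames(ov$regions[LEAF_CLUSTERS], LEAF_CLUSTERS)
  }
  uniq_go <- unique_region(go_sets)
  uniq_pw <- unique_region(pathway_sets)
  rows <- lapply(LEAF_CLUSTERS, function(lab) {
    ids <- cluster_members(memberships, lab)
    n <- length(ids)
    pr <- profiles[match(ids, profiles$gene_id), , drop = FALSE]
    if (anyNA(pr$gene_id) && n > 0) {
      stop_input("profiles missing for cluster ", lab)
    }
    ppi <- ppi_degree_summary(ids, ppi_edges, score_threshold,
                              score_direction, k = 1)
    n_prom <- sum(pr$promoter_read_count >= 1L)
    n_genic <- sum(pr$genic_read_count >= 1L)
    n_mirna <- sum(pr$mirna_count >= 1L)
    n_chromdb <- sum(pr$is_chromdb)
    n_tf <- if (is.null(tf_pairs)) NA_integer_ else
      sum(ids %in% tf_pairs$gene_id)
    n_pfam <- if (is.null(pfam_pairs)) NA_integer_ else
      sum(ids %in% pfam_pairs$gene_id)
    data.frame(
      cluster = lab, n_genes = n,
      mean_abs_fold_change = if (n) round(mean(fc[ids]), 2) else NA_real_,
      promoter_methylated = n_prom, pct_promoter = pct(n_prom, n),
      genic_methylated = n_genic, pct_genic = pct(n_genic, n),
      mirna_target = n_mirna, pct_mirna = pct(n_mirna, n),
      chromdb = n_chromdb, pct_chromdb = pct(n_chromdb, n),
      genes_with_ppi = ppi$n_genes_with_edge,
      pct_with_ppi = pct(ppi$n_genes_with_edge, n),
      tf_genes = n_tf, pct_tf = pct(n_tf, n),
      pfam_genes = n_pfam, pct_pfam = pct(n_pfam, n),
      unique_go_terms = as.integer(uniq_go[lab]),
      unique_pathways = as.integer(uniq_pw[lab]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
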