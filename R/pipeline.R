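# End-to-end orchestration: simulate/load -> map features -> classify ->
# enrich -> characterize, with deterministic TSV outputs and a run
# manifest written last.

#' Build a run configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or `inputs` (a named list of
#' file paths: `genes`, `drgs`, `reads`, `mirna`, `chromdb`, `tf`,
#' `pfam`, `pathway`, `go`, `ppi`) must be given. Thresholds default to
#' the pipeline's canonical settings; `score_direction` has no default
#' and must be chosen (`"ge"` treats PPI scores as confidence scores,
#' `"le"` as p-value-like).
#'
#' @param sim optional [sim_config()].
#' @param inputs optional named list of input file paths.
#' @param min_overlap genic overlap cutoff in bases.
#' @param promoter_len promoter window length in bases.
#' @param promoter_min_overlap promoter overlap cutoff in bases.
#' @param bg_size random background list size.
#' @param n_draws Monte Carlo background draws.
#' @param alpha significance level for term enrichment.
#' @param min_mapped minimum mapped entries per term.
#' @param score_threshold,score_direction PPI score filter.
#' @param seed integer seed for all randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, inputs = NULL, min_overlap = 50,
                       promoter_len = 1000, promoter_min_overlap = 1,
                       bg_size = 5000, n_draws = 1000, alpha = 0.05,
                       min_mapped = 5, score_threshold = 0.04,
                       score_direction = c("ge", "le"), seed = 1) {
  score_direction <- match.arg(score_direction)
  if (is.null(sim) == is.null(inputs)) {
    stop_input("exactly one of 'sim' or 'inputs' must be given")
  }
  if (!is.null(inputs)) {
    need <- c("genes", "drgs", "reads", "mirna", "chromdb", "tf", "pfam",
              "pathway", "go", "ppi")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop_input("run config missing input path(s): ",
                 paste(miss, collapse = ", "))
    }
  }
  if (min_overlap < 1 || promoter_min_overlap < 1 || promoter_len < 1) {
    stop_input("overlap cutoffs and promoter_len must be >= 1")
  }
  if (n_draws < 2) stop_input("n_draws must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop_input("alpha must lie in (0, 1)")
  structure(list(sim = sim, inputs = inputs, min_overlap = min_overlap,
                 promoter_len = promoter_len,
                 promoter_min_overlap = promoter_min_overlap,
                 bg_size = bg_size, n_draws = n_draws, alpha = alpha,
                 min_mapped = min_mapped,
                 score_threshold = score_threshold,
                 score_direction = score_direction, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim:` mapping
#' is passed to [sim_config()], an `inputs:` mapping gives file paths.
#'
#' @param path YAML file.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(run_config, y)
}

load_bundle <- function(inputs) {
  list(genes = read_gene_models(inputs$genes, format = "tsv"),
       drgs = read_drg_table(inputs$drgs),
       reads = read_intervals_bed(inputs$reads),
       mirna = read_pair_table(inputs$mirna, "mirna_target"),
       chromdb = read_pair_table(inputs$chromdb, "chromdb"),
       tf = read_pair_table(inputs$tf, "tf_family"),
       pfam = read_pair_table(inputs$pfam, "pfam"),
       pathway = read_pair_table(inputs$pathway, "pathway"),
       go = read_go_annotations(inputs$go),
       ppi = read_pair_table(inputs$ppi, "ppi_edge"),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Chains simulate/load, feature mapping, cluster classification,
#' enrichment statistics and cluster characterization; writes every stage
#' output as TSV under `out_dir` and a `manifest.json` last. With an
#' identical config (including seed) and identical inputs the TSV outputs
#' are byte-identical across runs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory stage results
#'   (`bundle`, `profiles`, `memberships`, `enrichment`, `go_enrichment`,
#'   `summary`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[epidrg] ", ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("stage 1/5: inputs")
  bundle <- if (!is.null(config$sim)) simulate_dataset(config$sim) else
    load_bundle(config$inputs)
  genes <- bundle$genes
  say("  ", nrow(genes), " genes, ", length(unique(bundle$drgs$gene_id)),
      " DRGs, ", nrow(bundle$reads), " methylation reads")

  say("stage 2/5: feature mapping")
  genic <- map_reads_to_genic(genes, bundle$reads,
                              min_overlap = config$min_overlap)
  windows <- promoter_windows(genes, upstream = config$promoter_len)
  prom <- map_reads_to_promoters(windows, bundle$reads,
                                 min_overlap = config$promoter_min_overlap)
  profiles <- build_feature_profiles(
    genes, genic, prom, bundle$mirna, bundle$chromdb, bundle$reads,
    min_overlap = config$min_overlap,
    promoter_min_overlap = config$promoter_min_overlap
  )
  write_tsv(profiles[, !vapply(profiles, is.list, TRUE)],
            file.path(out_dir, "profiles.tsv"))

  say("stage 3/5: cluster classification")
  memberships <- classify(bundle$drgs, profiles)
  violations <- validate_partition(memberships)
  if (nrow(violations)) {
    warning("cluster partition violations detected; see manifest",
            call. = FALSE)
  }
  write_tsv(memberships, file.path(out_dir, "clusters.tsv"))
  fc_summary <- fold_change_summary(memberships, bundle$drgs)
  write_tsv(fc_summary, file.path(out_dir, "fold_change_summary.tsv"))

  say("stage 4/5: enrichment statistics")
  pool <- eligible_pool(genes)
  drg_ids <- cluster_members(memberships, "D")
  feature_sets <- list(
    genic = unique(genic$gene_id),
    promoter = unique(prom$gene_id),
    mirna = profiles$gene_id[profiles$mirna_count >= 1L],
    chromdb = profiles$gene_id[profiles$is_chromdb]
  )
  enrichment <- do.call(rbind, lapply(names(feature_sets), function(f) {
    mc <- mc_enrichment_z(drg_ids, feature_sets[[f]], pool,
                          n_draws = config$n_draws, seed = config$seed,
                          feature = f)
    bn <- binomial_z(drg_ids, feature_sets[[f]], pool, feature = f)
    rbind(mc, bn)
  }))
  write_tsv(enrichment, file.path(out_dir, "enrichment_z.tsv"))
  go_enrichment <- lapply(setNames(LEAF_CLUSTERS, LEAF_CLUSTERS),
                          function(lab) {
    res <- fisher_term_enrichment(
      intersect(cluster_members(memberships, lab), pool), bundle$go,
      pool, min_mapped = config$min_mapped, alpha = config$alpha)
    write_tsv(res, file.path(out_dir,
                             paste0("go_enrichment_", lab, ".tsv")))
    res
  })

  say("stage 5/5: characterization")
  for (kind in c("tf", "pfam", "pathway")) {
    dist <- family_distribution(memberships, bundle[[kind]])
    write_tsv(dist, file.path(out_dir, paste0(kind, "_distribution.tsv")))
  }
  ppi_rows <- lapply(LEAF_CLUSTERS, function(lab) {
    s <- ppi_degree_summary(cluster_members(memberships, lab), bundle$ppi,
                            config$score_threshold,
                            config$score_direction)
    data.frame(cluster = lab, n_genes = s$n_genes,
               n_genes_with_edge = s$n_genes_with_edge,
               total_edges_within = s$total_edges_within,
               mean_degree_all = round(s$mean_degree_all, 3),
               mean_degree_positive = round(s$mean_degree_positive, 3),
               top_genes = paste(s$top_genes$gene_id, collapse = ","),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, ppi_rows), file.path(out_dir, "ppi_summary.tsv"))

  go_sets <- lapply(go_enrichment, function(res) res$term_id[res$enriched])
  leaf_sets <- function(pairs) {
    lapply(setNames(LEAF_CLUSTERS, LEAF_CLUSTERS), function(lab) {
      unique(pairs$subject_id[pairs$gene_id %in%
                                cluster_members(memberships, lab)])
    })
  }
  overlap_kinds <- list(go = go_sets, tf = leaf_sets(bundle$tf),
                        pfam = leaf_sets(bundle$pfam),
                        pathway = leaf_sets(bundle$pathway))
  overlaps <- do.call(rbind, lapply(names(overlap_kinds), function(kind) {
    ov <- four_set_overlap(overlap_kinds[[kind]])
    data.frame(kind = kind, region = names(ov$regions),
               count = as.integer(ov$regions), stringsAsFactors = FALSE)
  }))
  write_tsv(overlaps, file.path(out_dir, "overlap_counts.tsv"))
  summary_tab <- cluster_summary_table(
    memberships, bundle$drgs, profiles, bundle$ppi,
    tf_pairs = bundle$tf, pfam_pairs = bundle$pfam,
    go_sets = go_sets, pathway_sets = overlap_kinds$pathway,
    score_threshold = config$score_threshold,
    score_direction = config$score_direction
  )
  write_tsv(summary_tab, file.path(out_dir, "cluster_summary.tsv"))

  manifest <- list(
    tool = "epidrg",
    version = as.character(utils::packageVersion("epidrg")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config_echo(config),
    input_checksums = if (is.null(config$inputs)) NULL else
      as.list(tools::md5sum(unlist(config$inputs))),
    row_counts = list(genes = nrow(genes), drgs = nrow(bundle$drgs),
                      reads = nrow(bundle$reads),
                      genic_assignments = nrow(genic),
                      promoter_assignments = nrow(prom),
                      drg_clusters = nrow(memberships)),
    partition_violations = nrow(violations)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; outputs in ", out_dir)
  invisible(list(bundle = bundle, profiles = profiles,
                 memberships = memberships, enrichment = enrichment,
                 go_enrichment = go_enrichment, summary = summary_tab,
                 manifest = manifest))
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$sim)) out$sim <- unclass(out$sim)
  out
}
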