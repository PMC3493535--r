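# Synthetic input bundles with planted, configurable enrichments.
#
# The generator emits every table the pipeline consumes (gene models, DRG
# list, methylation read intervals, miRNA targets, chromatin genes, TF
# families, Pfam families, pathways, GO annotations, PPI edges) plus the
# planted ground truth, so that every downstream stage can be validated
# against known effects without external data.
#
# Planting model: per-gene Bernoulli on "carries >= 1 instance" of each
# feature, with the DRG rate rho-fold the non-DRG base rate (capped at 1),
# and instance counts drawn conditionally from a geometric so multiplicity
# histograms are non-trivial. Genes are placed sequentially per chromosome
# with exponential inter-gene gaps and never overlap.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the rice drought analysis the
#' pipeline reimplements: 55986 gene models of which 5468 are DRGs with
#' 43.7% upregulated; per-feature base rates and enrichment factors chosen
#' so the realized DRG prevalences match the reported ones (genic
#' methylation 40%, promoter methylation 12%, miRNA targets 32%,
#' chromatin genes 1.6%); planted lognormal fold-change means of 15 (up)
#' and 3 (down). Effect sizes beyond prevalence are calibration choices,
#' not reported values.
#'
#' @param n_genes,n_chroms number of gene models and chromosomes.
#' @param te_fraction,pseudo_fraction fractions of TE and pseudogene
#'   models (mutually exclusive classes).
#' @param n_drg,up_fraction DRG count and upregulated fraction.
#' @param n_reads number of background (intergenic noise) methylation
#'   reads on top of the planted per-gene reads.
#' @param read_len methylation read length in bases.
#' @param mean_gene_len,sigma_gene_len lognormal gene-length parameters
#'   (mean on the natural scale; genes are clamped to >= 150 bases).
#' @param mean_gap mean exponential inter-gene gap in bases.
#' @param p0_genic,p0_promoter,p0_mirna,p0_chromdb non-DRG base rates of
#'   carrying >= 1 feature instance.
#' @param rho_genic,rho_promoter,rho_mirna,rho_chromdb DRG/non-DRG
#'   enrichment factors (planted rate `min(1, rho * p0)`).
#' @param fold_change_lognormal_params named vector `mu_up`, `mu_down`,
#'   `sigma` of the per-direction lognormal fold changes.
#' @param n_mirnas,n_go_terms,n_tf_families,n_pfam_families,n_pathways
#'   annotation vocabulary sizes.
#' @param tf_rate,pfam_rate,pathway_rate per-gene membership rates.
#' @param go_mean_terms mean number of baseline GO annotations per gene.
#' @param n_spike_go,spike_rate,spike_base_rate GO terms planted into the
#'   feature-positive upregulated DRGs (the EU-like set) at `spike_rate`
#'   vs `spike_base_rate` elsewhere.
#' @param ppi_density_down,ppi_density_up expected within-group PPI edges
#'   per gene among down- / up-regulated DRGs (downregulated clusters are
#'   denser, as observed in the study).
#' @param ppi_density_base expected background edges per gene over all
#'   genes.
#' @param seed integer seed; one global seed expands into per-table
#'   substreams, so adding a table never perturbs earlier tables.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 55986, n_chroms = 12,
                       te_fraction = 0.29, pseudo_fraction = 0.02,
                       n_drg = 5468, up_fraction = 0.437,
                       n_reads = round(0.01 * n_genes), read_len = 75,
                       mean_gene_len = 3000, sigma_gene_len = 0.7,
                       mean_gap = 3000,
                       p0_genic = 0.20, rho_genic = 2,
                       p0_promoter = 0.06, rho_promoter = 2,
                       p0_mirna = 0.12, rho_mirna = 2.7,
                       p0_chromdb = 0.009, rho_chromdb = 1.8,
                       fold_change_lognormal_params =
                         c(mu_up = log(15) - 0.5, mu_down = log(3) - 0.5,
                           sigma = 1),
                       n_mirnas = 300, n_go_terms = 200,
                       n_tf_families = 80, n_pfam_families = 300,
                       n_pathways = 100,
                       tf_rate = 0.043, pfam_rate = 0.60,
                       pathway_rate = 0.08, go_mean_terms = 2,
                       n_spike_go = 4, spike_rate = 0.3,
                       spike_base_rate = 0.02,
                       ppi_density_down = 2, ppi_density_up = 0.7,
                       ppi_density_base = 0.02,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(te_fraction, pseudo_fraction, up_fraction,
             p0_genic, p0_promoter, p0_mirna, p0_chromdb,
             tf_rate, pfam_rate, pathway_rate, spike_rate,
             spike_base_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop_input("fractions and rates must lie in [0, 1]")
  }
  if (any(c(rho_genic, rho_promoter, rho_mirna, rho_chromdb) < 0)) {
    stop_input("enrichment factors rho must be >= 0")
  }
  n_eligible <- floor(n_genes * (1 - te_fraction - pseudo_fraction))
  if (n_drg > n_eligible) {
    stop_input("infeasible config: n_drg (", n_drg,
               ") exceeds eligible non-TE, non-pseudogene genes (",
               n_eligible, ")")
  }
  needed <- c("mu_up", "mu_down", "sigma")
  if (!all(needed %in% names(fold_change_lognormal_params))) {
    stop_input("fold_change_lognormal_params needs mu_up, mu_down, sigma")
  }
  structure(cfg, class = "sim_config")
}

plant_feature <- function(n_genes, is_drg, p0, rho) {
  p <- ifelse(is_drg, pmin(1, rho * p0), p0)
  rbinom(n_genes, 1L, p) == 1L
}

place_reads_in <- function(lo, hi, counts, read_len, prefix) {
  # place `counts[i]` reads of length read_len (clipped to the region)
  # uniformly within [lo[i], hi[i]]
  idx <- rep.int(seq_along(counts), counts)
  width <- hi[idx] - lo[idx] + 1L
  rl <- pmin(read_len, width)
  maxstart <- hi[idx] - rl + 1L
  start <- lo[idx] + floor(runif(length(idx)) * (maxstart - lo[idx] + 1L))
  data.frame(read_id = sprintf("%s_%06d", prefix, seq_along(idx)),
             start = as.integer(start),
             end = as.integer(start + rl - 1L),
             gene_idx = idx, stringsAsFactors = FALSE)
}

#' Simulate a complete input bundle with planted enrichments
#'
#' Deterministic under the config seed (identical seed, identical
#' bundle); every emitted table satisfies the reader invariants of the
#' I/O layer.
#'
#' @param config a [sim_config()].
#' @return list with elements `genes`, `drgs`, `reads`, `mirna`,
#'   `chromdb`, `tf`, `pfam`, `pathway`, `go`, `ppi` (canonical tables)
#'   and `truth` (planted ground truth: DRG ids, per-feature planted
#'   positive sets, enrichment factors, spiked GO terms, config echo).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  seed <- cfg$seed

  ## gene models -------------------------------------------------------
  genes <- with_sub_seed(seed, "genes", {
    n <- cfg$n_genes
    chrom_of <- sort(rep_len(seq_len(cfg$n_chroms), n))
    sigma <- cfg$sigma_gene_len
    len <- pmax(150L, as.integer(round(rlnorm(
      n, log(cfg$mean_gene_len) - sigma^2 / 2, sigma))))
    # gaps of at least twice the promoter length keep every 1 kb
    # upstream window inside its own intergenic space, so planted genic
    # and promoter reads cannot cross-contaminate neighbouring genes
    gap <- 2000L + as.integer(round(rexp(n, 1 / cfg$mean_gap)))
    # leading offset leaves room for a full promoter window
    start <- integer(n)
    end <- integer(n)
    for (ch in seq_len(cfg$n_chroms)) {
      i <- which(chrom_of == ch)
      s <- 1500L + cumsum(c(0L, (len[i] + gap[i] + 1L)[-length(i)]))
      start[i] <- s
      end[i] <- s + len[i] - 1L
    }
    cls <- sample(c("te", "pseudo", "ok"), n, replace = TRUE,
                  prob = c(cfg$te_fraction, cfg$pseudo_fraction,
                           1 - cfg$te_fraction - cfg$pseudo_fraction))
    data.frame(gene_id = sprintf("g%06d", seq_len(n)),
               chrom = paste0("chr", chrom_of),
               start = start, end = end,
               strand = sample(c("+", "-"), n, replace = TRUE),
               is_te = cls == "te", is_pseudogene = cls == "pseudo",
               stringsAsFactors = FALSE)
  })
  n <- nrow(genes)
  eligible <- !genes$is_te & !genes$is_pseudogene

  ## DRG table ---------------------------------------------------------
  fcp <- cfg$fold_change_lognormal_params
  drg_idx <- with_sub_seed(seed, "drgs",
                           sort(sample(which(eligible), cfg$n_drg)))
  is_drg <- seq_len(n) %in% drg_idx
  drgs <- with_sub_seed(seed, "drg_directions", {
    up <- runif(cfg$n_drg) < cfg$up_fraction
    mu <- ifelse(up, fcp[["mu_up"]], fcp[["mu_down"]])
    data.frame(gene_id = genes$gene_id[drg_idx],
               direction = ifelse(up, "up", "down"),
               fold_change = rlnorm(cfg$n_drg, mu, fcp[["sigma"]]),
               source = "simulated", stringsAsFactors = FALSE)
  })
  up_ids <- drgs$gene_id[drgs$direction == "up"]
  down_ids <- drgs$gene_id[drgs$direction == "down"]

  ## methylation reads -------------------------------------------------
  genic_pos <- with_sub_seed(seed, "plant_genic",
                             plant_feature(n, is_drg, cfg$p0_genic,
                                           cfg$rho_genic))
  prom_pos <- with_sub_seed(seed, "plant_promoter",
                            plant_feature(n, is_drg, cfg$p0_promoter,
                                          cfg$rho_promoter))
  windows <- promoter_windows(genes)
  prom_pos <- prom_pos & !windows$degenerate &
    (windows$end - windows$start + 1L) >= 1L
  reads <- with_sub_seed(seed, "reads", {
    g_counts <- ifelse(genic_pos, 1L + rgeom(n, 0.5), 0L)
    genic <- place_reads_in(genes$start, genes$end, g_counts,
                            cfg$read_len, "gread")
    p_counts <- ifelse(prom_pos, 1L + rgeom(n, 0.7), 0L)
    prom <- place_reads_in(windows$start, windows$end, p_counts,
                           cfg$read_len, "pread")
    chrom_len <- tapply(genes$end, genes$chrom, max) + 5000L
    noise_chrom <- sample(names(chrom_len), cfg$n_reads, replace = TRUE)
    noise_start <- as.integer(
      1L + floor(runif(cfg$n_reads) * (chrom_len[noise_chrom] -
                                         cfg$read_len)))
    out <- rbind(
      data.frame(read_id = genic$read_id,
                 chrom = genes$chrom[genic$gene_idx],
                 start = genic$start, end = genic$end,
                 stringsAsFactors = FALSE),
      data.frame(read_id = prom$read_id,
                 chrom = genes$chrom[prom$gene_idx],
                 start = prom$start, end = prom$end,
                 stringsAsFactors = FALSE),
      data.frame(read_id = sprintf("nread_%06d", seq_len(cfg$n_reads)),
                 chrom = noise_chrom, start = noise_start,
                 end = noise_start + as.integer(cfg$read_len) - 1L,
                 stringsAsFactors = FALSE)
    )
    rownames(out) <- NULL
    out
  })

  ## miRNA targets -----------------------------------------------------
  mirna_pool <- sprintf("osa-sim-miR%04d", seq_len(cfg$n_mirnas))
  mirna_pos <- with_sub_seed(seed, "plant_mirna",
                             plant_feature(n, is_drg, cfg$p0_mirna,
                                           cfg$rho_mirna))
  mirna <- with_sub_seed(seed, "mirna", {
    counts <- ifelse(mirna_pos, pmin(1L + rgeom(n, 0.4), cfg$n_mirnas), 0L)
    idx <- rep.int(seq_len(n), counts)
    subj <- unlist(lapply(counts[counts > 0L],
                          function(k) sample(mirna_pool, k)),
                   use.names = FALSE)
    data.frame(subject_id = subj, gene_id = genes$gene_id[idx],
               score = NA_real_, kind = "mirna_target",
               stringsAsFactors = FALSE)
  })

  ## chromatin-associated genes ---------------------------------------
  chromdb_pos <- with_sub_seed(seed, "plant_chromdb",
                               plant_feature(n, is_drg, cfg$p0_chromdb,
                                             cfg$rho_chromdb))
  n_cap <- sum(chromdb_pos)
  chromdb <- data.frame(subject_id = rep("CAP", n_cap),
                        gene_id = genes$gene_id[chromdb_pos],
                        score = rep(NA_real_, n_cap),
                        kind = rep("chromdb", n_cap),
                        stringsAsFactors = FALSE)

  ## TF families, Pfam families, pathways ------------------------------
  zipf_sample <- function(vocab, counts) {
    counts <- pmin(counts, length(vocab))
    idx <- rep.int(seq_len(n), counts)
    w <- 1 / seq_along(vocab)
    subj <- unlist(lapply(counts[counts > 0L], function(k) {
      sample(vocab, k, prob = w)
    }), use.names = FALSE)
    data.frame(subject_id = subj, gene_id = genes$gene_id[idx],
               stringsAsFactors = FALSE)
  }
  tf <- with_sub_seed(seed, "tf", {
    memb <- rbinom(n, 1L, cfg$tf_rate) == 1L
    fam <- sprintf("TF_fam_%02d", seq_len(cfg$n_tf_families))
    out <- zipf_sample(fam, as.integer(memb))
    data.frame(out, score = NA_real_, kind = "tf_family",
               stringsAsFactors = FALSE)
  })
  pfam <- with_sub_seed(seed, "pfam", {
    counts <- ifelse(rbinom(n, 1L, cfg$pfam_rate) == 1L,
                     1L + rgeom(n, 0.6), 0L)
    fam <- sprintf("PF_sim_%04d", seq_len(cfg$n_pfam_families))
    out <- zipf_sample(fam, counts)
    out <- out[!duplicated(out), , drop = FALSE]
    data.frame(out, score = NA_real_, kind = "pfam",
               stringsAsFactors = FALSE)
  })
  pathway <- with_sub_seed(seed, "pathway", {
    counts <- ifelse(rbinom(n, 1L, cfg$pathway_rate) == 1L,
                     1L + rgeom(n, 0.7), 0L)
    pw <- sprintf("PWY_sim_%03d", seq_len(cfg$n_pathways))
    out <- zipf_sample(pw, counts)
    out <- out[!duplicated(out), , drop = FALSE]
    data.frame(out, score = NA_real_, kind = "pathway",
               stringsAsFactors = FALSE)
  })

  ## GO annotations with spiked terms ----------------------------------
  any_feat <- genic_pos | prom_pos | mirna_pos | chromdb_pos
  eu_like <- genes$gene_id %in% up_ids & any_feat
  go_vocab <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  spike_terms <- if (cfg$n_spike_go > 0) {
    utils::tail(go_vocab, cfg$n_spike_go)
  } else character()
  base_vocab <- setdiff(go_vocab, spike_terms)
  go <- with_sub_seed(seed, "go", {
    counts <- rpois(n, cfg$go_mean_terms)
    base <- zipf_sample(base_vocab, counts)
    spike_rows <- lapply(spike_terms, function(term) {
      p <- ifelse(eu_like, cfg$spike_rate, cfg$spike_base_rate)
      hit <- rbinom(n, 1L, p) == 1L
      data.frame(subject_id = term, gene_id = genes$gene_id[hit],
                 stringsAsFactors = FALSE)
    })
    out <- rbind(base, do.call(rbind, spike_rows))
    out <- out[!duplicated(out), , drop = FALSE]
    data.frame(out, score = NA_real_, kind = "go", aspect = "P",
               stringsAsFactors = FALSE)
  })

  ## PPI edges ---------------------------------------------------------
  sample_edges <- function(ids, n_edges) {
    if (n_edges < 1L || length(ids) < 2L) {
      return(data.frame(subject_id = character(), gene_id = character(),
                        stringsAsFactors = FALSE))
    }
    a <- sample(ids, n_edges, replace = TRUE)
    b <- sample(ids, n_edges, replace = TRUE)
    data.frame(subject_id = a, gene_id = b, stringsAsFactors = FALSE)
  }
  ppi <- with_sub_seed(seed, "ppi", {
    raw <- rbind(
      sample_edges(down_ids,
                   round(cfg$ppi_density_down * length(down_ids) / 2)),
      sample_edges(up_ids,
                   round(cfg$ppi_density_up * length(up_ids) / 2)),
      sample_edges(genes$gene_id, round(cfg$ppi_density_base * n / 2))
    )
    raw$score <- runif(nrow(raw))
    raw$kind <- "ppi_edge"
    canonicalize_ppi(raw)
  })
  rownames(ppi) <- NULL

  truth <- list(
    drg_ids = drgs$gene_id, up_ids = up_ids, down_ids = down_ids,
    planted = list(genic = genes$gene_id[genic_pos],
                   promoter = genes$gene_id[prom_pos],
                   mirna = genes$gene_id[mirna_pos],
                   chromdb = genes$gene_id[chromdb_pos]),
    rho = c(genic = cfg$rho_genic, promoter = cfg$rho_promoter,
            mirna = cfg$rho_mirna, chromdb = cfg$rho_chromdb),
    p0 = c(genic = cfg$p0_genic, promoter = cfg$p0_promoter,
           mirna = cfg$p0_mirna, chromdb = cfg$p0_chromdb),
    spike_go = list(terms = spike_terms, cluster = "EU"),
    config = unclass(cfg)
  )
  list(genes = genes, drgs = drgs, reads = reads, mirna = mirna,
       chromdb = chromdb, tf = tf, pfam = pfam, pathway = pathway,
       go = go, ppi = ppi, truth = truth)
}

#' Realized DRG/background feature enrichment ratio
#'
#' Observed prevalence ratio of a feature between the DRG set and its
#' complement, recomputed from the emitted bundle (not from the planted
#' flags): methylation features are re-derived by interval mapping at the
#' pipeline thresholds, annotation features from the pair tables. Returns
#' `Inf` (unbounded) when the feature is absent outside the DRGs but
#' present inside, and `NaN` when absent everywhere.
#'
#' @param bundle output of [simulate_dataset()].
#' @param truth the bundle's ground truth (supplies the DRG ids).
#' @param feature `"genic"`, `"promoter"`, `"mirna"` or `"chromdb"`.
#' @return the prevalence ratio (a single number).
#' @export
realized_enrichment <- function(bundle, truth,
                                feature = c("genic", "promoter", "mirna",
                                            "chromdb")) {
  feature <- match.arg(feature)
  genes <- bundle$genes
  pos_ids <- switch(feature,
    genic = unique(map_reads_to_genic(genes, bundle$reads)$gene_id),
    promoter = unique(map_reads_to_promoters(
      promoter_windows(genes), bundle$reads)$gene_id),
    mirna = unique(bundle$mirna$gene_id),
    chromdb = unique(bundle$chromdb$gene_id)
  )
  drg <- truth$drg_ids
  non_drg <- setdiff(genes$gene_id, drg)
  r_drg <- mean(drg %in% pos_ids)
  r_bg <- mean(non_drg %in% pos_ids)
  if (r_bg == 0 && r_drg > 0) return(Inf)
  if (r_bg == 0 && r_drg == 0) return(NaN)
  r_drg / r_bg
}

#' Write a simulated bundle to a directory
#'
#' Emits the bundle in the pipeline's file formats: `genes.tsv`,
#' `drgs.tsv`, `reads.bed`, one TSV per pair table and `truth.json`.
#'
#' @param bundle output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$genes, file.path(dir, "genes.tsv"))
  write_tsv(bundle$drgs, file.path(dir, "drgs.tsv"))
  write_bed(bundle$reads, file.path(dir, "reads.bed"))
  for (nm in c("mirna", "chromdb", "tf", "pfam", "pathway", "ppi")) {
    write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  # GO goes out in the GAF-like layout the GO reader expects
  write_tsv(data.frame(gene_id = bundle$go$gene_id,
                       go_id = bundle$go$subject_id,
                       aspect = bundle$go$aspect),
            file.path(dir, "go.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
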