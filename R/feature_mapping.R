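# Mapping methylation read intervals onto genic spans and promoter windows,
# and assembling per-gene feature profiles.
#
# The genic region is the full TSS-to-gene-end span (no exon structure).
# Overlap is counted in shared 1-based positions: a read is assigned to a
# region iff they lie on the same chromosome and share at least
# `min_overlap` bases. The default genic cutoff is 50 bases; promoter
# assignment defaults to any overlap (min_overlap = 1), since the 50-base
# rule is stated for genic reads only.

genes_granges <- function(df, id_col = "gene_id") {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    id = df[[id_col]]
  )
}

overlap_assignments <- function(region_df, reads, min_overlap, id_col) {
  if (min_overlap < 1) stop_input("min_overlap must be >= 1")
  if (nrow(region_df) == 0L || nrow(reads) == 0L) {
    return(data.frame(gene_id = character(), read_id = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- GenomicRanges::findOverlaps(
    genes_granges(reads, "read_id"), genes_granges(region_df, id_col),
    minoverlap = min_overlap, ignore.strand = TRUE
  )
  out <- data.frame(
    gene_id = region_df[[id_col]][S4Vectors::subjectHits(hits)],
    read_id = reads$read_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  out[order(out$gene_id, out$read_id), , drop = FALSE]
}

#' Assign methylation reads to genic regions
#'
#' A read is assigned to every gene whose span it overlaps by at least
#' `min_overlap` bases on the same chromosome; reads overlapping two genes
#' count for both (no arbitration).
#'
#' @param genes gene-model table ([read_gene_models()]).
#' @param reads read-interval table ([read_intervals_bed()]).
#' @param min_overlap minimum shared bases (default 50).
#' @return data.frame of assignments with columns `gene_id`, `read_id`.
#' @export
map_reads_to_genic <- function(genes, reads, min_overlap = 50) {
  overlap_assignments(genes, reads, min_overlap, "gene_id")
}

#' Promoter windows upstream of the TSS
#'
#' Strand-aware by default: for a `+` gene the window is
#' `[max(1, start - upstream), start - 1]`; for a `-` gene it is
#' `[end + 1, end + upstream]`. The window abuts but never overlaps the
#' gene span. A `+` gene starting at position 1 yields a degenerate empty
#' window (flagged); windows shortened by the chromosome start are flagged
#' `truncated`. `ignore_strand = TRUE` reproduces a strand-naive reading
#' where every window lies left of `start`.
#'
#' @param genes gene-model table.
#' @param upstream window length in bases (default 1000).
#' @param ignore_strand treat all genes as `+`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `truncated`, `degenerate`.
#' @export
promoter_windows <- function(genes, upstream = 1000, ignore_strand = FALSE) {
  if (upstream < 1) stop_input("upstream must be >= 1")
  plus <- if (ignore_strand) rep(TRUE, nrow(genes)) else genes$strand == "+"
  ws <- ifelse(plus, pmax(1L, genes$start - as.integer(upstream)),
               genes$end + 1L)
  we <- ifelse(plus, genes$start - 1L, genes$end + as.integer(upstream))
  degenerate <- we < ws
  truncated <- !degenerate & (we - ws + 1L) < upstream
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(ifelse(degenerate, 1L, ws)),
    end = as.integer(ifelse(degenerate, 0L, we)),
    strand = genes$strand, truncated = truncated, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Assign methylation reads to promoter windows
#'
#' Same overlap contract as [map_reads_to_genic()] but with its own
#' threshold: the default `min_overlap = 1` classifies any read touching
#' the upstream window as a promoter read. Degenerate windows (genes at
#' the chromosome start) receive no assignments.
#'
#' @param windows promoter windows from [promoter_windows()].
#' @param reads read-interval table.
#' @param min_overlap minimum shared bases (default 1).
#' @return data.frame of assignments with columns `gene_id`, `read_id`.
#' @export
map_reads_to_promoters <- function(windows, reads, min_overlap = 1) {
  live <- windows[!windows$degenerate, , drop = FALSE]
  overlap_assignments(live, reads, min_overlap, "gene_id")
}

ids_by_gene <- function(assignments, gene_ids) {
  sp <- split(assignments$read_id, factor(assignments$gene_id,
                                          levels = gene_ids))
  lapply(sp, function(x) sort(unique(x)))
}

filter_known <- function(pairs, gene_ids, what) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(pairs)
  unknown <- !(pairs$gene_id %in% gene_ids)
  if (any(unknown)) {
    warning(sum(unknown), " ", what, " pair(s) reference unknown gene_id; ",
            "skipped", call. = FALSE)
    pairs <- pairs[!unknown, , drop = FALSE]
  }
  pairs
}

#' Assemble per-gene feature profiles
#'
#' One row per gene in `genes`; genes absent from an annotation table get
#' zero counts / `FALSE` flags. Besides the genic and promoter read counts,
#' two strand-aware sub-window counts are computed with the same overlap
#' thresholds as their parent regions: reads among a gene's genic
#' assignments that also overlap the first 1000 genic bases from the TSS,
#' and reads among its promoter assignments that also overlap the 200 bases
#' immediately upstream of the TSS.
#'
#' @param genes gene-model table.
#' @param genic genic assignments ([map_reads_to_genic()]).
#' @param promoter promoter assignments ([map_reads_to_promoters()]).
#' @param mirna_pairs miRNA-target pair table (`kind = "mirna_target"`) or
#'   `NULL`.
#' @param chromdb_pairs chromatin-gene pair table (`kind = "chromdb"`) or
#'   `NULL`.
#' @param reads read-interval table (needed for the sub-window counts).
#' @param min_overlap genic overlap threshold used for the first-1kb
#'   sub-window (default 50).
#' @param promoter_min_overlap promoter overlap threshold used for the
#'   first-200 sub-window (default 1).
#' @param ignore_strand strand-naive sub-windows (see
#'   [promoter_windows()]).
#' @return data.frame with counts, id list-columns and the `is_chromdb`
#'   flag; one row per gene.
#' @export
build_feature_profiles <- function(genes, genic, promoter,
                                   mirna_pairs = NULL, chromdb_pairs = NULL,
                                   reads = NULL, min_overlap = 50,
                                   promoter_min_overlap = 1,
                                   ignore_strand = FALSE) {
  gid <- genes$gene_id
  genic_ids <- ids_by_gene(genic, gid)
  prom_ids <- ids_by_gene(promoter, gid)
  mirna_pairs <- filter_known(mirna_pairs, gid, "miRNA-target")
  chromdb_pairs <- filter_known(chromdb_pairs, gid, "chromdb")
  mirna_ids <- if (is.null(mirna_pairs)) {
    rep(list(character()), length(gid))
  } else {
    sp <- split(mirna_pairs$subject_id, factor(mirna_pairs$gene_id,
                                               levels = gid))
    lapply(sp, function(x) sort(unique(x)))
  }
  is_chromdb <- if (is.null(chromdb_pairs)) rep(FALSE, length(gid)) else
    gid %in% chromdb_pairs$gene_id

  first1kb <- first200 <- rep(0L, length(gid))
  if (!is.null(reads) && nrow(reads)) {
    plus <- if (ignore_strand) rep(TRUE, nrow(genes)) else
      genes$strand == "+"
    # first 1000 genic bases from the TSS, clipped to the gene span
    kb <- data.frame(
      gene_id = gid, chrom = genes$chrom,
      start = ifelse(plus, genes$start, pmax(genes$start, genes$end - 999L)),
      end = ifelse(plus, pmin(genes$end, genes$start + 999L), genes$end),
      stringsAsFactors = FALSE
    )
    kb_asgn <- overlap_assignments(kb, reads, min_overlap, "gene_id")
    kb_asgn <- intersect_pairs(kb_asgn, genic)
    first1kb <- pair_counts(kb_asgn, gid)
    # 200 bases immediately upstream of the TSS
    w200 <- promoter_windows(genes, upstream = 200,
                             ignore_strand = ignore_strand)
    w200_asgn <- map_reads_to_promoters(w200, reads,
                                        min_overlap = promoter_min_overlap)
    w200_asgn <- intersect_pairs(w200_asgn, promoter)
    first200 <- pair_counts(w200_asgn, gid)
  }

  out <- data.frame(gene_id = gid,
                    genic_read_count = lengths(genic_ids),
                    promoter_read_count = lengths(prom_ids),
                    mirna_count = lengths(mirna_ids),
                    is_chromdb = is_chromdb,
                    first1kb_read_count = first1kb,
                    first200_promoter_count = first200,
                    stringsAsFactors = FALSE)
  out$genic_read_ids <- I(unname(genic_ids))
  out$promoter_read_ids <- I(unname(prom_ids))
  out$mirna_ids <- I(unname(mirna_ids))
  rownames(out) <- NULL
  out
}

intersect_pairs <- function(a, b) {
  key <- function(d) paste(d$gene_id, d$read_id, sep = "\r")
  a[key(a) %in% key(b), , drop = FALSE]
}

pair_counts <- function(assignments, gene_ids) {
  as.integer(table(factor(assignments$gene_id, levels = gene_ids)))
}

feature_flags <- function(profiles) {
  cbind(genic = profiles$genic_read_count >= 1L,
        promoter = profiles$promoter_read_count >= 1L,
        mirna = profiles$mirna_count >= 1L,
        chromdb = profiles$is_chromdb)
}

#' Feature co-occurrence summary
#'
#' For the four features (genic methylation, promoter methylation, miRNA
#' target, chromdb membership) over a gene universe: genes carrying ONLY
#' one feature, all pairwise intersections, the genic/promoter/miRNA
#' triple, genes with any feature and genes with none.
#'
#' @param profiles feature profiles ([build_feature_profiles()]).
#' @param universe gene ids to restrict to (default all profiled genes).
#' @return list with elements `unique` (named length-4), `pairwise`
#'   (named length-6), `triple_genic_promoter_mirna`, `any`, `none`.
#' @export
feature_cooccurrence <- function(profiles, universe = profiles$gene_id) {
  if (!all(universe %in% profiles$gene_id)) {
    stop_input("universe contains genes without profiles")
  }
  f <- feature_flags(profiles)[match(universe, profiles$gene_id), ,
                               drop = FALSE]
  nfeat <- rowSums(f)
  uni <- colSums(f & nfeat == 1L)
  feats <- colnames(f)
  pairs <- utils::combn(feats, 2)
  pw <- apply(pairs, 2, function(p) sum(f[, p[1]] & f[, p[2]]))
  names(pw) <- apply(pairs, 2, paste, collapse = "_")
  list(unique = uni,
       pairwise = pw,
       triple_genic_promoter_mirna =
         sum(f[, "genic"] & f[, "promoter"] & f[, "mirna"]),
       any = sum(nfeat >= 1L),
       none = sum(nfeat == 0L))
}

#' Mean gene lengths per named partition
#'
#' @param genes gene-model table.
#' @param partitions named list of gene-id sets.
#' @return data.frame with columns `partition`, `n_genes`, `mean_length`
#'   (`NA` for empty sets, never 0).
#' @export
length_summary <- function(genes, partitions) {
  stopifnot(is.list(partitions), !is.null(names(partitions)))
  len <- genes$end - genes$start + 1L
  names(len) <- genes$gene_id
  rows <- lapply(names(partitions), function(nm) {
    ids <- partitions[[nm]]
    if (!all(ids %in% genes$gene_id)) {
      stop_input("partition '", nm, "' contains unknown gene ids")
    }
    data.frame(partition = nm, n_genes = length(ids),
               mean_length = if (length(ids)) mean(len[ids]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Histogram of per-gene feature multiplicity
#'
#' Distribution of instance counts among genes carrying at least one
#' instance of the feature; the histogram total equals the number of
#' feature-positive genes.
#'
#' @param profiles feature profiles.
#' @param feature `"genic"`, `"promoter"` or `"mirna"`.
#' @return data.frame with columns `n_instances`, `n_genes`.
#' @export
multiplicity_histogram <- function(profiles,
                                   feature = c("genic", "promoter",
                                               "mirna")) {
  feature <- match.arg(feature)
  col <- switch(feature, genic = "genic_read_count",
                promoter = "promoter_read_count", mirna = "mirna_count")
  x <- profiles[[col]]
  x <- x[x >= 1L]
  if (!length(x)) {
    return(data.frame(n_instances = integer(), n_genes = integer()))
  }
  tab <- table(x)
  data.frame(n_instances = as.integer(names(tab)),
             n_genes = as.integer(tab))
}
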