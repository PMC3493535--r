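# Readers and writers for all pipeline inputs/outputs.
#
# Internal coordinate convention: 1-based, fully inclusive, on both ends
# (GFF3 style). Only the BED reader/writer converts from/to BED's 0-based
# half-open [chromStart, chromEnd). Readers are strict by default: a row
# that violates a type invariant is a fatal error naming the offending
# line, unless skip_bad_rows = TRUE, which drops such rows with a warning
# giving the count.

PAIR_KINDS <- c("mirna_target", "chromdb", "tf_family", "pfam", "pathway",
                "go", "ppi_edge")

CLUSTER_LABELS <- c("D", "DU", "DD", "E", "NE", "EU", "ED", "NEU", "NED")

#' Read gene models from GFF3 or TSV
#'
#' Only `gene`-type records are read from GFF3; no feature hierarchy is
#' resolved. TE and pseudogene status must be declared explicitly: in GFF3
#' via the attributes `is_te=` and `is_pseudogene=` (values `1/0`,
#' `true/false`; absent means `FALSE`), in TSV via logical columns of the
#' same names. Status is never inferred from identifiers.
#'
#' @param path input file.
#' @param format `"gff3"` or `"tsv"`. A TSV needs columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `is_te`, `is_pseudogene`.
#' @param skip_bad_rows drop invalid rows (with a warning) instead of
#'   erroring.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`+`/`-`), `is_te`, `is_pseudogene`.
#' @export
read_gene_models <- function(path, format = c("gff3", "tsv"),
                             skip_bad_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "gff3") {
    df <- parse_gff3_genes(path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand",
              "is_te", "is_pseudogene")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop_input("missing column(s): ",
                                 paste(miss, collapse = ", "))
    df <- df[need]
    df$line <- seq_len(nrow(df)) + 1L  # header is line 1
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$is_te <- as.logical(df$is_te)
  df$is_pseudogene <- as.logical(df$is_pseudogene)
  bad <- is.na(df$start) | is.na(df$end) | df$start > df$end |
    !(df$strand %in% c("+", "-")) | is.na(df$is_te) | is.na(df$is_pseudogene)
  df <- drop_or_die(df, bad, path, "invalid gene record", skip_bad_rows)
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop_input("duplicate gene_id in ", path, ": ",
               paste(unique(df$gene_id[dup]), collapse = ", "))
  }
  df$line <- NULL
  rownames(df) <- NULL
  df
}

parse_gff3_genes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop_input("malformed GFF3 line ", idx[which(nf != 9L)[1L]], " in ",
               path, ": expected 9 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  gene <- m[, 3] == "gene"
  m <- m[gene, , drop = FALSE]
  idx <- idx[gene]
  attr_get <- function(attrs, key) {
    m <- regexec(paste0("(^|;)\\s*", key, "=([^;]*)"), attrs)
    vapply(regmatches(attrs, m),
           function(g) if (length(g) >= 3L) g[3L] else NA_character_, "")
  }
  attrs <- if (nrow(m)) m[, 9] else character()
  ids <- attr_get(attrs, "ID")
  if (any(is.na(ids))) {
    stop_input("GFF3 line ", idx[which(is.na(ids))[1L]], " in ", path,
               ": gene record without ID attribute")
  }
  flag <- function(x) !is.na(x) & tolower(x) %in% c("1", "true", "yes")
  data.frame(
    gene_id = ids,
    chrom = m[, 1],
    start = suppressWarnings(as.integer(m[, 4])),
    end = suppressWarnings(as.integer(m[, 5])),
    strand = m[, 7],
    is_te = flag(attr_get(attrs, "is_te")),
    is_pseudogene = flag(attr_get(attrs, "is_pseudogene")),
    line = idx,
    stringsAsFactors = FALSE
  )
}

drop_or_die <- function(df, bad, path, what, skip_bad_rows) {
  if (!any(bad)) return(df)
  if (skip_bad_rows) {
    warning(sum(bad), " ", what, "(s) skipped in ", path, call. = FALSE)
    return(df[!bad, , drop = FALSE])
  }
  stop_input(what, " at line ", df$line[which(bad)[1L]], " of ", path)
}

#' Read methylation read intervals from BED
#'
#' BED coordinates (0-based, half-open) are converted to the internal
#' 1-based inclusive convention: `[chromStart, chromEnd)` becomes
#' `[chromStart + 1, chromEnd]`, preserving interval length. A fourth
#' column, when present, supplies `read_id`; otherwise ids are generated.
#'
#' @inheritParams read_gene_models
#' @return data.frame with columns `read_id`, `chrom`, `start`, `end`.
#' @export
read_intervals_bed <- function(path, skip_bad_rows = FALSE) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track|browser|$)", lines)
  idx <- which(keep)
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_input("malformed BED line ", idx[which(nf < 3L)[1L]], " in ", path,
               ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  bstart <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  bend <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  ids <- ifelse(nf >= 4L, vapply(fields, `[`, "", 4L), NA_character_)
  auto <- is.na(ids) | ids == "."
  ids[auto] <- sprintf("read_%06d", which(auto))
  df <- data.frame(read_id = ids, chrom = chrom,
                   start = bstart + 1L, end = bend,
                   line = idx, stringsAsFactors = FALSE)
  bad <- is.na(bstart) | is.na(bend) | bend <= bstart | bstart < 0L
  df <- drop_or_die(df, bad, path, "invalid BED interval", skip_bad_rows)
  if (anyDuplicated(df$read_id)) {
    stop_input("duplicate read_id in ", path)
  }
  df$line <- NULL
  rownames(df) <- NULL
  df
}

#' Write methylation read intervals as BED4
#'
#' Inverse of [read_intervals_bed()]: internal 1-based inclusive intervals
#' are written back as 0-based half-open BED records.
#'
#' @param reads data.frame as returned by [read_intervals_bed()].
#' @param path output file.
#' @export
write_bed <- function(reads, path) {
  out <- data.frame(chrom = reads$chrom, start = reads$start - 1L,
                    end = reads$end, name = reads$read_id)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the DRG table
#'
#' Expects a TSV with header and columns `gene_id`, `direction`
#' (`up`/`down`), `fold_change` (absolute fold change, > 0) and optionally
#' `source` (study label; defaults to `"study"`). A gene may appear on
#' several rows when reported by several studies.
#'
#' @inheritParams read_gene_models
#' @return data.frame with columns `gene_id`, `direction`, `fold_change`,
#'   `source`.
#' @export
read_drg_table <- function(path, skip_bad_rows = FALSE) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "direction", "fold_change")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("missing column(s): ",
                               paste(miss, collapse = ", "))
  if (is.null(df$source)) df$source <- "study"
  df <- df[c("gene_id", "direction", "fold_change", "source")]
  df$fold_change <- as.numeric(df$fold_change)
  df$line <- seq_len(nrow(df)) + 1L
  bad <- !(df$direction %in% c("up", "down")) | is.na(df$fold_change) |
    df$fold_change <= 0
  df <- drop_or_die(df, bad, path, "invalid DRG record", skip_bad_rows)
  df$line <- NULL
  rownames(df) <- NULL
  df
}

#' Read a subject-gene annotation pair table
#'
#' Generic reader for the flat exports consumed by the pipeline: miRNA
#' targets, chromatin-gene membership, TF families, Pfam families, pathway
#' membership and PPI edges. Expects a TSV with header and columns
#' `subject_id`, `gene_id`, plus `score` for `kind = "ppi_edge"`.
#'
#' Pairs are deduplicated. PPI edges are stored undirected with
#' lexicographically ordered endpoints; self loops are dropped and
#' duplicated edges keep the maximum score. Scores must lie in \[0, 1\].
#'
#' @param path input TSV.
#' @param kind one of `r paste0('"', PAIR_KINDS, '"', collapse = ", ")`.
#' @return data.frame with columns `subject_id`, `gene_id`, `score`
#'   (`NA` unless `kind = "ppi_edge"`), `kind`.
#' @export
read_pair_table <- function(path, kind) {
  kind <- match.arg(kind, PAIR_KINDS)
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "gene_id", if (kind == "ppi_edge") "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("missing column(s): ",
                               paste(miss, collapse = ", "))
  df$score <- if (kind == "ppi_edge") as.numeric(df$score) else NA_real_
  df <- df[c("subject_id", "gene_id", "score")]
  df$kind <- kind
  if (kind == "ppi_edge") {
    if (any(is.na(df$score) | df$score < 0 | df$score > 1)) {
      stop_input("ppi_edge score outside [0, 1] in ", path)
    }
    df <- canonicalize_ppi(df)
  } else {
    df <- df[!duplicated(df[c("subject_id", "gene_id")]), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# Undirected simple-graph canonicalization: endpoints sorted, self loops
# removed, duplicates collapsed to their maximum score.
canonicalize_ppi <- function(df) {
  a <- pmin(df$subject_id, df$gene_id)
  b <- pmax(df$subject_id, df$gene_id)
  df$subject_id <- a
  df$gene_id <- b
  df <- df[a != b, , drop = FALSE]
  if (nrow(df)) {
    key <- paste(df$subject_id, df$gene_id, sep = "\r")
    mx <- tapply(df$score, key, max)
    df <- df[!duplicated(key), , drop = FALSE]
    df$score <- as.numeric(mx[paste(df$subject_id, df$gene_id, sep = "\r")])
    df <- df[order(df$subject_id, df$gene_id), , drop = FALSE]
  }
  df
}

#' Read GO annotations from a GAF-like TSV
#'
#' Expects columns `gene_id`, `go_id` and optionally `aspect` (P/F/C).
#' Returns the canonical pair-table layout with `subject_id = go_id` and
#' `kind = "go"`; annotations are used exactly as given (no propagation to
#' ancestor terms).
#'
#' @param path input TSV.
#' @return data.frame with columns `subject_id`, `gene_id`, `score`,
#'   `kind`, `aspect`.
#' @export
read_go_annotations <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "go_id"), names(df))
  if (length(miss)) stop_input("missing column(s): ",
                               paste(miss, collapse = ", "))
  out <- data.frame(subject_id = df$go_id, gene_id = df$gene_id,
                    score = NA_real_, kind = "go",
                    aspect = df$aspect %||% NA_character_,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("subject_id", "gene_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a canonical table as TSV
#'
#' Deterministic column order (as in the data.frame), header row, UTF-8,
#' tab separated, no quoting. List columns (e.g. per-gene read-id lists)
#' are collapsed with `","`. Tables written this way round-trip losslessly
#' through [read_tsv()].
#'
#' @param table data.frame.
#' @param path output file.
#' @export
write_tsv <- function(table, path) {
  if (is.null(table)) stop_input("table is NULL")
  tab <- as.data.frame(table)
  for (j in seq_along(tab)) {
    if (is.list(tab[[j]])) {
      tab[[j]] <- vapply(tab[[j]], function(x) paste(x, collapse = ","), "")
    }
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8", na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}
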