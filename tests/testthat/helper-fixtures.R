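# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (all-pairs loops, explicit enumeration)
# and independent of the implementation paths they check.

make_genes <- function(gene_id, chrom = "chr1", start, end, strand = "+",
                       is_te = FALSE, is_pseudogene = FALSE) {
  n <- length(gene_id)
  data.frame(gene_id = gene_id, chrom = rep_len(chrom, n),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), is_te = rep_len(is_te, n),
             is_pseudogene = rep_len(is_pseudogene, n),
             stringsAsFactors = FALSE)
}

make_reads <- function(read_id, chrom = "chr1", start, end) {
  data.frame(read_id = read_id, chrom = rep_len(chrom, length(read_id)),
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# all-pairs O(n*m) overlap oracle: shared 1-based positions per pair
brute_overlap <- function(genes, reads, min_overlap) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(reads))) {
      if (genes$chrom[i] != reads$chrom[j]) next
      ov <- min(genes$end[i], reads$end[j]) -
        max(genes$start[i], reads$start[j]) + 1L
      if (ov >= min_overlap) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], read_id = reads$read_id[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), read_id = character())
  out <- out[order(out$gene_id, out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_instance <- function(seed, n_genes = 30, n_reads = 60,
                            chroms = c("chr1", "chr2"), span = 20000) {
  set.seed(seed)
  gs <- sample.int(span - 2000, n_genes)
  rs <- sample.int(span, n_reads)
  list(
    genes = make_genes(sprintf("g%03d", seq_len(n_genes)),
                       chrom = sample(chroms, n_genes, replace = TRUE),
                       start = gs,
                       end = gs + sample(50:2000, n_genes, replace = TRUE),
                       strand = sample(c("+", "-"), n_genes,
                                       replace = TRUE)),
    reads = make_reads(sprintf("r%03d", seq_len(n_reads)),
                       chrom = sample(chroms, n_reads, replace = TRUE),
                       start = rs,
                       end = rs + sample(20:300, n_reads, replace = TRUE))
  )
}

small_sim <- function(seed, ...) {
  simulate_dataset(sim_config(n_genes = 600, n_chroms = 3, n_drg = 120,
                              n_reads = 10, seed = seed, ...))
}

# independently coded Benjamini-Yekutieli step-up
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m * cm / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# G = 2 * sum O ln(O/E), written out cell by cell
g_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  o <- c(a, b, c, d)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}

# exhaustive hypergeometric upper tail via binomial coefficients
hyper_tail_oracle <- function(k, K, N, n) {
  xs <- k:min(n, K)
  xs <- xs[n - xs <= N - K]
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

expect_same_assignments <- function(got, want) {
  got <- got[order(got$gene_id, got$read_id), , drop = FALSE]
  rownames(got) <- NULL
  expect_equal(got, want)
}
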