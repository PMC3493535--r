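test_that("genic assignment honours the 50-base overlap boundary", {
  genes <- make_genes("g1", start = 1001, end = 2000)
  # exactly 50 shared bases -> assigned; 49 -> not
  r50 <- make_reads("r1", start = 901, end = 1050)
  r49 <- make_reads("r2", start = 901, end = 1049)
  expect_equal(map_reads_to_genic(genes, r50)$gene_id, "g1")
  expect_equal(nrow(map_reads_to_genic(genes, r49)), 0L)
  # a read may be assigned to several overlapping genes
  genes2 <- make_genes(c("a", "b"), start = c(100, 400), end = c(500, 900))
  wide <- make_reads("r3", start = 350, end = 460)
  expect_equal(sort(map_reads_to_genic(genes2, wide)$gene_id), c("a", "b"))
})

test_that("genic and promoter mapping equal the all-pairs oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    for (mo in c(1L, 50L)) {
      expect_same_assignments(
        map_reads_to_genic(inst$genes, inst$reads, min_overlap = mo),
        brute_overlap(inst$genes, inst$reads, mo))
    }
    w <- promoter_windows(inst$genes)
    live <- w[!w$degenerate, c("gene_id", "chrom", "start", "end")]
    expect_same_assignments(
      map_reads_to_promoters(w, inst$reads),
      brute_overlap(live, inst$reads, 1L))
  }
})

test_that("raising min_overlap never increases assignment counts", {
  inst <- random_instance(99)
  sizes <- vapply(c(1, 10, 50, 100, 200), function(mo) {
    nrow(map_reads_to_genic(inst$genes, inst$reads, min_overlap = mo))
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("promoter windows are strand-aware, abut the gene and flag truncation", {
  g <- make_genes(c("p", "m", "t", "edge"),
                  start = c(5000, 2000, 500, 1),
                  end = c(6000, 5000, 900, 300),
                  strand = c("+", "-", "+", "+"))
  w <- promoter_windows(g)
  expect_equal(w$start[1], 4000L)  # + gene: [start-1000, start-1]
  expect_equal(w$end[1], 4999L)
  expect_equal(w$end[1] - w$start[1] + 1L, 1000L)
  expect_equal(w$start[2], 5001L)  # - gene: [end+1, end+1000]
  expect_equal(w$end[2], 6000L)
  expect_equal(w$start[3], 1L)     # truncated at chromosome start
  expect_equal(w$end[3], 499L)
  expect_true(w$truncated[3])
  expect_true(w$degenerate[4])     # gene starting at position 1

  # windows never intersect their own gene span
  inst <- random_instance(7)
  w2 <- promoter_windows(inst$genes)
  w2 <- w2[!w2$degenerate, ]
  g2 <- inst$genes[match(w2$gene_id, inst$genes$gene_id), ]
  ov <- pmin(w2$end, g2$end) - pmax(w2$start, g2$start) + 1L
  expect_true(all(ov <= 0L))
})

test_that("promoter threshold semantics: touch by 1 base counts at min_overlap 1 only", {
  g <- make_genes("g1", start = 5000, end = 6000)
  w <- promoter_windows(g)
  touch <- make_reads("r1", start = 4999 - 0, end = 5100)  # 1 base in window
  expect_equal(map_reads_to_promoters(w, touch)$gene_id, "g1")
  expect_equal(nrow(map_reads_to_promoters(w, touch, min_overlap = 50)), 0L)
})

test_that("strand flip invariance: mirrored coordinates preserve genic counts and map promoter windows onto each other", {
  inst <- random_instance(13)
  L <- 50000L
  mirror <- function(df) {
    s <- L - df$end + 1L
    e <- L - df$start + 1L
    df$start <- s
    df$end <- e
    if (!is.null(df$strand)) df$strand <- ifelse(df$strand == "+", "-", "+")
    df
  }
  a <- map_reads_to_genic(inst$genes, inst$reads)
  b <- map_reads_to_genic(mirror(inst$genes), mirror(inst$reads))
  expect_equal(table(a$gene_id), table(b$gene_id))
  w <- promoter_windows(inst$genes)
  wm <- promoter_windows(mirror(inst$genes))
  # truncation at the chromosome start has no mirror image (chromosomes
  # are unbounded to the right), so compare full windows only
  live <- !w$degenerate & !w$truncated
  expect_equal(mirror(w[live, c("gene_id", "start", "end")]),
               wm[live, c("gene_id", "start", "end")], ignore_attr = TRUE)
})

test_that("feature profiles assemble counts, sub-windows and zero rows", {
  genes <- make_genes(c("g1", "g2"), start = c(5000, 9000),
                      end = c(8000, 9500))
  reads <- make_reads(c("a", "b", "c"),
                      start = c(5100, 7000, 4500), end = c(5200, 7100, 4600))
  genic <- map_reads_to_genic(genes, reads)
  w <- promoter_windows(genes)
  prom <- map_reads_to_promoters(w, reads)
  mir <- data.frame(subject_id = c("m1", "m2", "m3"),
                    gene_id = c("g1", "g1", "g1"),
                    score = NA_real_, kind = "mirna_target")
  prof <- build_feature_profiles(genes, genic, prom, mir, NULL, reads)
  p1 <- prof[prof$gene_id == "g1", ]
  expect_equal(p1$genic_read_count, 2L)
  expect_equal(p1$promoter_read_count, 1L)  # read c in [4000, 4999]
  expect_equal(p1$mirna_count, 3L)
  expect_false(p1$is_chromdb)
  # read a lies in the first 1000 genic bases, read b does not
  expect_equal(p1$first1kb_read_count, 1L)
  # read c is not within 200 bases of the TSS
  expect_equal(p1$first200_promoter_count, 0L)
  p2 <- prof[prof$gene_id == "g2", ]
  expect_equal(p2$genic_read_count + p2$promoter_read_count +
                 p2$mirna_count, 0L)
  expect_identical(sort(p1$genic_read_ids[[1]]), c("a", "b"))
  # counts always equal the id-list lengths; sub-windows nest in parents
  expect_equal(prof$genic_read_count, lengths(prof$genic_read_ids))
  expect_equal(prof$promoter_read_count, lengths(prof$promoter_read_ids))
  expect_true(all(prof$first1kb_read_count <= prof$genic_read_count))
  expect_true(all(prof$first200_promoter_count <=
                    prof$promoter_read_count))
})

test_that("profile totals conserve the oracle count of qualifying pairs", {
  b <- small_sim(3)
  genic <- map_reads_to_genic(b$genes, b$reads)
  w <- promoter_windows(b$genes)
  prom <- map_reads_to_promoters(w, b$reads)
  prof <- build_feature_profiles(b$genes, genic, prom, b$mirna, b$chromdb,
                                 b$reads)
  expect_equal(sum(prof$genic_read_count),
               nrow(brute_overlap(b$genes, b$reads, 50L)))
  expect_equal(sum(prof$mirna_count), nrow(b$mirna))
  # unknown gene ids in a pair table are skipped with a warning
  mir_bad <- rbind(b$mirna,
                   data.frame(subject_id = "mX", gene_id = "nope",
                              score = NA_real_, kind = "mirna_target"))
  expect_warning(build_feature_profiles(b$genes, genic, prom, mir_bad,
                                        NULL, b$reads),
                 "unknown gene_id")
})

test_that("co-occurrence buckets equal a brute-force set-algebra oracle", {
  one <- function(genic, promoter, mirna, chromdb, id) {
    data.frame(gene_id = id, genic_read_count = genic,
               promoter_read_count = promoter, mirna_count = mirna,
               is_chromdb = chromdb, first1kb_read_count = 0L,
               first200_promoter_count = 0L)
  }
  p <- rbind(one(1, 0, 0, FALSE, "only_genic"),
             one(2, 1, 3, TRUE, "all_four"),
             one(0, 0, 0, FALSE, "none"))
  co <- feature_cooccurrence(p)
  expect_equal(unname(co$unique["genic"]), 1)
  expect_equal(unname(co$pairwise["genic_promoter"]), 1)
  expect_equal(co$triple_genic_promoter_mirna, 1)
  expect_equal(co$any, 2)
  expect_equal(co$none, 1)

  set.seed(5)
  n <- 200
  rp <- one(rbinom(n, 2, 0.4), rbinom(n, 2, 0.2), rbinom(n, 3, 0.3),
            runif(n) < 0.1, sprintf("g%03d", 1:n))
  co <- feature_cooccurrence(rp)
  f <- cbind(g = rp$genic_read_count > 0, p = rp$promoter_read_count > 0,
             m = rp$mirna_count > 0, c = rp$is_chromdb)
  expect_equal(unname(co$unique),
               unname(sapply(1:4, function(j)
                 sum(f[, j] & rowSums(f) == 1))))
  expect_equal(unname(co$pairwise["promoter_mirna"]),
               sum(f[, "p"] & f[, "m"]))
  expect_equal(co$any + co$none, n)
})

test_that("length summaries and multiplicity histograms match direct arithmetic", {
  g <- make_genes(c("a", "b", "c"), start = c(1, 1, 1),
                  end = c(1000, 3000, 500))
  ls <- length_summary(g, list(ab = c("a", "b"), empty = character()))
  expect_equal(ls$mean_length[ls$partition == "ab"], 2000)
  expect_true(is.na(ls$mean_length[ls$partition == "empty"]))

  p <- data.frame(gene_id = c("a", "b", "c", "d"),
                  genic_read_count = c(1L, 1L, 2L, 0L),
                  promoter_read_count = 0L, mirna_count = 0L,
                  is_chromdb = FALSE, first1kb_read_count = 0L,
                  first200_promoter_count = 0L)
  h <- multiplicity_histogram(p, "genic")
  expect_equal(h, data.frame(n_instances = c(1L, 2L), n_genes = c(2L, 1L)))
  expect_equal(sum(h$n_genes), sum(p$genic_read_count >= 1))
  expect_equal(nrow(multiplicity_histogram(p, "mirna")), 0L)
})
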