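mk_memberships <- function() {
  drgs <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    direction = c("up", "down", "up", "down"),
    fold_change = c(2, 4, 8, 1.5), source = "s")
  prof <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     genic_read_count = c(1L, 1L, 0L, 0L),
                     promoter_read_count = 0L,
                     mirna_count = c(0L, 2L, 0L, 0L),
                     is_chromdb = FALSE, first1kb_read_count = 0L,
                     first200_promoter_count = 0L)
  list(m = classify(drgs, prof), drgs = drgs, prof = prof)
}

test_that("family distributions count members per cluster with conserved sums", {
  x <- mk_memberships()   # g1 EU, g2 ED, g3 NEU, g4 NED
  pairs <- data.frame(subject_id = c("famA", "famA", "famB"),
                      gene_id = c("g1", "g2", "g3"),
                      score = NA_real_, kind = "tf_family")
  fd <- family_distribution(x$m, pairs,
                            genome_totals = c(famA = 10, famB = 4))
  a <- fd[fd$family_id == "famA", ]
  expect_equal(a$EU, 1L)
  expect_equal(a$ED, 1L)
  expect_equal(a$E, 2L)
  expect_equal(a$D, 2L)
  expect_equal(a$percent_drg_of_family, 20)
  # leaf counts sum to the family's D count
  expect_equal(fd$EU + fd$ED + fd$NEU + fd$NED, fd$D)
  expect_warning(family_distribution(x$m, pairs,
                                     genome_totals = c(famA = 10)),
                 "genome_totals")

  b <- small_sim(21)
  prof <- build_feature_profiles(
    b$genes, map_reads_to_genic(b$genes, b$reads),
    map_reads_to_promoters(promoter_windows(b$genes), b$reads),
    b$mirna, b$chromdb, b$reads)
  m <- classify(b$drgs, prof)
  fd2 <- family_distribution(m, b$pfam)
  expect_true(all(fd2$EU + fd2$ED + fd2$NEU + fd2$NED == fd2$D))
  expect_true(all(fd2$DU + fd2$DD == fd2$D))
})

test_that("PPI degree summaries count within-cluster filtered edges only", {
  tri <- data.frame(subject_id = c("a", "a", "b"),
                    gene_id = c("b", "c", "c"),
                    score = c(0.9, 0.8, 0.7), kind = "ppi_edge")
  s <- ppi_degree_summary(c("a", "b", "c"), tri, 0.5, "ge")
  expect_equal(s$mean_degree_all, 2)
  expect_equal(s$total_edges_within, 3L)
  # edges to genes outside the cluster contribute no degree
  s2 <- ppi_degree_summary(c("a", "z"), tri, 0.5, "ge")
  expect_equal(s2$mean_degree_all, 0)
  expect_equal(s2$n_genes_with_edge, 0L)
  # score filter direction is explicit
  s3 <- ppi_degree_summary(c("a", "b", "c"), tri, 0.75, "le")
  expect_equal(s3$total_edges_within, 1L)
  expect_error(ppi_degree_summary("a", tri, 0.5, "ge", k = 0), "k must")

  # random graph: degrees equal an adjacency-count oracle, the filter is
  # monotone, and edge-list row order is irrelevant
  set.seed(33)
  ids <- sprintf("n%02d", 1:15)
  raw <- data.frame(subject_id = sample(ids, 60, TRUE),
                    gene_id = sample(ids, 60, TRUE),
                    score = runif(60), kind = "ppi_edge")
  edges <- epidrg:::canonicalize_ppi(raw)
  s4 <- ppi_degree_summary(ids, edges, 0.3, "ge", k = 15)
  kept <- edges[edges$score >= 0.3, ]
  deg_oracle <- vapply(ids, function(g)
    sum(kept$subject_id == g) + sum(kept$gene_id == g), 0L)
  got <- setNames(s4$top_genes$degree, s4$top_genes$gene_id)[ids]
  expect_equal(unname(got), unname(deg_oracle))
  s5 <- ppi_degree_summary(ids, edges, 0, "ge", k = 15)
  expect_true(all(s5$top_genes$degree[order(s5$top_genes$gene_id)] >=
                    s4$top_genes$degree[order(s4$top_genes$gene_id)]))
  shuf <- edges[sample(nrow(edges)), ]
  expect_equal(ppi_degree_summary(ids, shuf, 0.3, "ge", k = 15), s4)
  # ties in top-k break by gene id ascending
  expect_equal(s4$top_genes$gene_id,
               s4$top_genes$gene_id[order(-s4$top_genes$degree,
                                          s4$top_genes$gene_id)])
})

test_that("four-set overlap counts all 15 regions and sums to the union", {
  ov <- four_set_overlap(list(A = "a", B = "a", C = character(),
                              D = character()))
  expect_equal(unname(ov$regions["A&B"]), 1L)
  expect_equal(sum(ov$regions), 1L)
  ov2 <- four_set_overlap(list(A = "w", B = "x", C = "y", D = "z"))
  expect_equal(unname(ov2$regions[c("A", "B", "C", "D")]), rep(1L, 4))
  expect_equal(sum(ov2$regions), 4L)
  expect_error(four_set_overlap(list(A = "a", A = "b", C = "c", D = "d")),
               "distinct")
  expect_error(four_set_overlap(list(A = "a", B = "b")), "exactly 4")

  set.seed(8)
  for (i in 1:20) {
    sets <- lapply(1:4, function(j) sample(letters, sample(0:20, 1)))
    names(sets) <- c("p", "q", "r", "s")
    ov3 <- four_set_overlap(sets)
    u <- unique(unlist(sets))
    expect_equal(sum(ov3$regions), length(u))
    # brute-force oracle: classify each element by its membership vector
    for (el in u) {
      inside <- names(sets)[vapply(sets, function(s) el %in% s, TRUE)]
      key <- paste(inside, collapse = "&")
      expect_gte(ov3$regions[key], 1L)
    }
  }
})

test_that("the consolidated summary recomputes percents from raw tables", {
  x <- mk_memberships()
  edges <- data.frame(subject_id = "g2", gene_id = "g4", score = 0.9,
                      kind = "ppi_edge")
  tf <- data.frame(subject_id = "famA", gene_id = "g3", score = NA_real_,
                   kind = "tf_family")
  go_sets <- list(EU = c("GO:1", "GO:2"), ED = "GO:2", NEU = character(),
                  NED = "GO:3")
  tab <- cluster_summary_table(x$m, x$drgs, x$prof, edges, tf_pairs = tf,
                               pfam_pairs = NULL, go_sets = go_sets,
                               pathway_sets = NULL,
                               score_threshold = 0.5,
                               score_direction = "ge")
  eu <- tab[tab$cluster == "EU", ]
  expect_equal(eu$n_genes, 1L)
  expect_equal(eu$genic_methylated, 1L)
  expect_equal(eu$pct_genic, 100)
  expect_equal(eu$unique_go_terms, 1L)       # GO:1 only in EU
  ed <- tab[tab$cluster == "ED", ]
  expect_equal(ed$mirna_target, 1L)
  expect_equal(ed$pct_mirna, 100)
  # NE-derived clusters have all-zero epigenetic/miRNA features by definition
  ne <- tab[tab$cluster %in% c("NEU", "NED"), ]
  expect_true(all(ne$genic_methylated == 0 & ne$promoter_methylated == 0 &
                    ne$mirna_target == 0 & ne$chromdb == 0))
  # within-cluster PPI: the g2-g4 edge spans ED and NED, so neither counts
  expect_equal(sum(tab$genes_with_ppi), 0L)
  expect_equal(tab$tf_genes[tab$cluster == "NEU"], 1L)

  # percent columns always re-derive from counts and sizes
  expect_equal(tab$pct_genic, pct(tab$genic_methylated, tab$n_genes))
  expect_equal(tab$pct_tf, pct(tab$tf_genes, tab$n_genes))
  expect_error(cluster_summary_table(x$m, x$drgs, x$prof, edges,
                                     go_sets = list(EU = "a"),
                                     score_direction = "ge"),
               "missing leaf")
})
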