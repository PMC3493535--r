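test_that("background sampling excludes TE/pseudogenes but retains DRGs", {
  g <- make_genes(sprintf("g%02d", 1:10), start = 1:10 * 100,
                  end = 1:10 * 100 + 50,
                  is_te = c(rep(TRUE, 2), rep(FALSE, 8)))
  s <- sample_background(g, size = 8, seed = 1)
  expect_length(s, 8)
  expect_false(any(s %in% c("g01", "g02")))
  expect_error(sample_background(g, size = 9), "exceeds")
  expect_identical(sample_background(g, 5, seed = 3),
                   sample_background(g, 5, seed = 3))

  # drawing from a pool that is 15% DRG-flagged keeps that fraction:
  # mean DRG share over seeded draws sits inside the binomial 99% CI
  g2 <- make_genes(sprintf("x%04d", 1:2000), start = 1:2000 * 10,
                   end = 1:2000 * 10 + 5)
  drg <- g2$gene_id[1:300]
  fracs <- vapply(1:200, function(s)
    mean(sample_background(g2, 400, seed = s) %in% drg), 0)
  n_tot <- 200 * 400
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.15) / n_tot
  expect_gte(mean(fracs), ci[1])
  expect_lte(mean(fracs), ci[2])
})

test_that("Monte Carlo z handles exact-null and degenerate pools", {
  pool <- sprintf("g%03d", 1:100)
  # feature in every pool gene: every draw equals the query size
  r <- mc_enrichment_z(pool[1:10], pool, pool, n_draws = 50, seed = 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$z))
  expect_error(mc_enrichment_z(character(), pool, pool), "empty query")
  # determinism under (seed, B)
  fp <- pool[1:30]
  a <- mc_enrichment_z(pool[1:20], fp, pool, n_draws = 100, seed = 9)
  b <- mc_enrichment_z(pool[1:20], fp, pool, n_draws = 100, seed = 9)
  expect_identical(a, b)
})

test_that("binomial z matches the closed form and the MC estimate converges to it", {
  pool <- sprintf("g%04d", 1:1000)
  fp <- pool[1:100]                       # p0 = 0.1
  query <- c(pool[1:20], pool[901:980])   # n = 100, observed = 20
  r <- binomial_z(query, fp, pool)
  expect_equal(r$z, 10 / 3, tolerance = 1e-12)
  # observed equal to expectation gives z = 0
  pool2 <- sprintf("h%03d", 1:200)
  q2 <- c(pool2[1:50], pool2[101:150])
  r2 <- binomial_z(q2, pool2[1:100], pool2)  # p0=0.5, n=100, obs=50
  expect_equal(r2$z, 0)
  expect_equal(r2$p_two_sided, 1)
  # degenerate prevalence
  expect_true(binomial_z(pool[1:5], character(), pool)$degenerate)

  # convergence: |mc - binomial| small at large B on a fixed fixture
  mc <- mc_enrichment_z(query, fp, pool, n_draws = 1e4, seed = 42)
  expect_lt(abs(mc$z - r$z), 0.2)
})

test_that("Fisher enrichment equals exhaustive enumeration and filters before testing", {
  bg <- sprintf("g%03d", 1:100)
  query <- bg[1:10]
  ann <- data.frame(subject_id = "T1", gene_id = c(bg[1:5], bg[11:15]),
                    score = NA_real_, kind = "go")
  res <- fisher_term_enrichment(query, ann, bg, min_mapped = 5)
  expect_equal(res$k_set, 5L)
  expect_equal(res$k_bg, 10L)
  expect_equal(res$p_raw, hyper_tail_oracle(5, 10, 100, 10),
               tolerance = 1e-12)

  # a term annotating every background gene is never enriched
  all_ann <- data.frame(subject_id = "ALL", gene_id = bg,
                        score = NA_real_, kind = "go")
  expect_equal(fisher_term_enrichment(query, all_ann, bg)$p_raw, 1)

  # the min_mapped filter drops terms BEFORE adjustment
  ann2 <- rbind(ann, data.frame(subject_id = "T2", gene_id = bg[1:2],
                                score = NA_real_, kind = "go"))
  res2 <- fisher_term_enrichment(query, ann2, bg, min_mapped = 5)
  expect_equal(res2$term_id, "T1")
  res3 <- fisher_term_enrichment(query, ann2, bg, min_mapped = 1)
  expect_setequal(res3$term_id, c("T1", "T2"))

  expect_error(fisher_term_enrichment(c(query, "zzz"), ann, bg), "subset")
  expect_error(fisher_term_enrichment(query, ann, character()), "empty")
})

test_that("BY adjustment matches the hand formula and an independent step-up", {
  expect_equal(by_adjust(0.04), 0.04)
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(by_adjust(rep(0.2, 5)), rep(by_adjust(rep(0.2, 5))[1], 5))
  expect_error(by_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    adj <- by_adjust(p)
    expect_equal(adj, by_oracle(p), tolerance = 1e-12)
    # BY dominates BH elementwise and respects permutations
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-12))
    perm <- sample(seq_along(p))
    expect_equal(by_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("G statistic matches its direct formula, symmetries and the chi-square null", {
  expect_equal(g_statistic(matrix(c(10, 10, 90, 90), 2))$g, 0)
  expect_equal(g_statistic(matrix(c(10, 10, 90, 90), 2))$p, 1)
  tab <- matrix(c(20, 10, 80, 90), 2)   # rows (20,80) and (10,90)
  expect_equal(g_statistic(tab)$g, 3.986556, tolerance = 1e-5)
  expect_equal(g_statistic(tab)$g, g_oracle(20, 80, 10, 90),
               tolerance = 1e-12)
  expect_equal(g_statistic(tab[2:1, ])$g, g_statistic(tab)$g)
  expect_equal(g_statistic(tab[, 2:1])$g, g_statistic(tab)$g)
  expect_error(g_statistic(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(g_statistic(matrix(1:6, 2)), "2x2")

  set.seed(23)
  for (i in 1:100) {
    cells <- matrix(rpois(4, 40) + 1, 2)
    expect_equal(g_statistic(cells)$g,
                 g_oracle(cells[1, 1], cells[1, 2], cells[2, 1],
                          cells[2, 2]), tolerance = 1e-10)
  }

  # asymptotics: G on independent tables follows chi-square(1)
  set.seed(31)
  gs <- replicate(600, {
    r <- rbinom(2, 400, 0.3)
    g_statistic(matrix(c(r[1], 400 - r[1], r[2], 400 - r[2]), 2,
                       byrow = TRUE))$g
  })
  expect_gt(suppressWarnings(
    stats::ks.test(gs, stats::pchisq, df = 1)$p.value), 0.01)
})
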