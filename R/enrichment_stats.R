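# Statistical machinery: random-gene background construction, Monte Carlo
# z-score enrichment with a closed-form binomial cross-check, Fisher exact
# term enrichment with Benjamini-Yekutieli correction and a
# minimum-mapping filter, and the G likelihood-ratio statistic for 2x2
# contingency enrichment.

#' Eligible background gene pool
#'
#' All genes except transposable-element and pseudogene models. DRGs are
#' NOT excluded: leaving them in keeps the background an unbiased draw
#' from the gene universe.
#'
#' @param genes gene-model table.
#' @return character vector of gene ids.
#' @export
eligible_pool <- function(genes) {
  genes$gene_id[!genes$is_te & !genes$is_pseudogene]
}

#' Sample a random background gene list
#'
#' Uniform sample without replacement from the eligible pool
#' ([eligible_pool()]), deterministic under `seed`.
#'
#' @param genes gene-model table.
#' @param size number of genes to draw (default 5000).
#' @param seed integer seed.
#' @return character vector of `size` gene ids.
#' @export
sample_background <- function(genes, size = 5000, seed = 1) {
  pool <- eligible_pool(genes)
  if (size > length(pool)) {
    stop_input("requested background size ", size,
               " exceeds eligible pool (", length(pool), ")")
  }
  with_sub_seed(seed, "background", sample(pool, size))
}

enrichment_result <- function(feature, observed, n, bg_mean, bg_sd, z, p,
                              method, degenerate = FALSE) {
  data.frame(feature = feature, observed = observed, target_size = n,
             bg_mean = bg_mean, bg_sd = bg_sd, z = z, p_two_sided = p,
             method = method, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Monte Carlo enrichment z-score
#'
#' Observed count of feature-positive genes in `query`, standardized
#' against `n_draws` random gene sets of the same size drawn (without
#' replacement, seeded) from the background pool:
#' `z = (observed - mean_B) / sd_B` with the `B - 1` denominator in
#' `sd_B`; two-sided p from the standard normal. When every draw yields
#' the same count (`sd_B = 0`) the result is flagged degenerate and `z`
#' is `NA`.
#'
#' @param query gene-id set being tested (e.g. the DRGs or one cluster).
#' @param feature_positive gene ids carrying the feature.
#' @param pool background pool to draw from ([eligible_pool()]).
#' @param n_draws number of Monte Carlo background draws (default 1000).
#' @param seed integer seed.
#' @param feature label carried into the result row.
#' @return one-row data.frame (`feature`, `observed`, `target_size`,
#'   `bg_mean`, `bg_sd`, `z`, `p_two_sided`, `method`, `degenerate`).
#' @export
mc_enrichment_z <- function(query, feature_positive, pool, n_draws = 1000,
                            seed = 1, feature = "feature") {
  if (!length(query)) stop_input("empty query set")
  if (n_draws < 2) stop_input("n_draws must be >= 2")
  if (length(query) > length(pool)) {
    stop_input("query larger than the background pool")
  }
  observed <- length(intersect(query, feature_positive))
  fp <- pool %in% feature_positive
  n <- length(query)
  counts <- with_sub_seed(seed, "mc_enrichment", {
    vapply(seq_len(n_draws),
           function(i) sum(fp[sample.int(length(pool), n)]), 0L)
  })
  m <- mean(counts)
  s <- sd(counts)
  if (s == 0) {
    return(enrichment_result(feature, observed, n, m, 0, NA_real_,
                             NA_real_, "monte_carlo", degenerate = TRUE))
  }
  z <- (observed - m) / s
  enrichment_result(feature, observed, n, m, s, z, 2 * pnorm(-abs(z)),
                    "monte_carlo")
}

#' Closed-form binomial enrichment z-score
#'
#' Analytic cross-check of [mc_enrichment_z()]: with feature prevalence
#' `p0` in the pool, `z = (observed - n p0) / sqrt(n p0 (1 - p0))` for a
#' query of size `n`. Degenerate (z undefined) when `p0` is 0 or 1.
#'
#' @inheritParams mc_enrichment_z
#' @return one-row data.frame as in [mc_enrichment_z()].
#' @export
binomial_z <- function(query, feature_positive, pool,
                       feature = "feature") {
  if (!length(query)) stop_input("empty query set")
  if (!length(pool)) stop_input("empty pool")
  observed <- length(intersect(query, feature_positive))
  n <- length(query)
  p0 <- mean(pool %in% feature_positive)
  if (p0 %in% c(0, 1)) {
    return(enrichment_result(feature, observed, n, n * p0, 0, NA_real_,
                             NA_real_, "binomial", degenerate = TRUE))
  }
  s <- sqrt(n * p0 * (1 - p0))
  z <- (observed - n * p0) / s
  enrichment_result(feature, observed, n, n * p0, s, z,
                    2 * pnorm(-abs(z)), "binomial")
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `adj_(i) = min_(j >= i) p_(j) * m * c(m) / j` with
#' `c(m) = sum_(k=1..m) 1/k`, clipped at 1 and mapped back to the input
#' order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
by_adjust <- function(p_values) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BY")
}

#' Fisher exact term enrichment with BY correction
#'
#' For each annotation term: `k_set` genes of the query and `k_bg` genes
#' of the background carry the term. Terms with fewer than `min_mapped`
#' mapped entries are dropped BEFORE testing (query-set count by default,
#' configurable to the background count). Surviving terms get a one-sided
#' hypergeometric upper-tail p (Fisher exact test for enrichment) and a
#' Benjamini-Yekutieli adjustment across the surviving terms of this
#' query only.
#'
#' @param query gene-id set, a subset of `background`.
#' @param annotations pair table of one term kind (e.g. `kind = "go"`).
#' @param background background gene-id set.
#' @param min_mapped minimum mapped entries per term (default 5).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param filter_on `"query"` (default) or `"background"`: which count
#'   the `min_mapped` filter applies to.
#' @return data.frame, one row per surviving term, sorted by `p_raw`:
#'   `term_id`, `k_set`, `n_set`, `k_bg`, `n_bg`, `p_raw`, `p_adjusted`,
#'   `enriched`.
#' @export
fisher_term_enrichment <- function(query, annotations, background,
                                   min_mapped = 5, alpha = 0.05,
                                   filter_on = c("query", "background")) {
  filter_on <- match.arg(filter_on)
  if (!length(background)) stop_input("empty background")
  if (!all(query %in% background)) {
    stop_input("query must be a subset of the background")
  }
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  n_set <- length(query)
  n_bg <- length(background)
  k_bg <- table(ann$subject_id)
  in_q <- ann[ann$gene_id %in% query, , drop = FALSE]
  k_set <- table(factor(in_q$subject_id, levels = names(k_bg)))
  keep <- if (filter_on == "query") k_set >= min_mapped else
    k_bg >= min_mapped
  terms <- names(k_bg)[keep]
  if (!length(terms)) {
    return(data.frame(term_id = character(), k_set = integer(),
                      n_set = integer(), k_bg = integer(),
                      n_bg = integer(), p_raw = numeric(),
                      p_adjusted = numeric(), enriched = logical()))
  }
  ks <- as.integer(k_set[terms])
  kb <- as.integer(k_bg[terms])
  # upper tail P(X >= k_set), X ~ Hypergeom(k_bg, n_bg - k_bg, n_set)
  p_raw <- phyper(ks - 1L, kb, n_bg - kb, n_set, lower.tail = FALSE)
  p_adj <- by_adjust(p_raw)
  out <- data.frame(term_id = terms, k_set = ks, n_set = n_set,
                    k_bg = kb, n_bg = n_bg, p_raw = p_raw,
                    p_adjusted = p_adj, enriched = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' G likelihood-ratio statistic for a 2x2 table
#'
#' `G = 2 * sum O * ln(O / E)` with expected cells from the margins under
#' independence and the `0 * ln(0) = 0` convention; p from chi-square with
#' 1 degree of freedom. No correction by default; `williams = TRUE`
#' divides G by the Williams correction factor.
#'
#' @param table 2x2 matrix of nonnegative counts; no zero row or column
#'   margin.
#' @param williams apply the Williams correction.
#' @return list with elements `table`, `g`, `p`, `df`.
#' @export
g_statistic <- function(table, williams = FALSE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop_input("table must be 2x2")
  if (any(tab < 0)) stop_input("counts must be nonnegative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop_input("zero row/column margin")
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  g <- 2 * sum(ifelse(tab > 0, tab * log(tab / expected), 0))
  if (williams) {
    q <- 1 + (sum(n / rs) - 1) * (sum(n / cs) - 1) / (6 * n)
    g <- g / q
  }
  list(table = tab, g = g, p = pchisq(g, df = 1, lower.tail = FALSE),
       df = 1L)
}
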