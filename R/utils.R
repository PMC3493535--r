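#' Percentage of a count over a total
#'
#' Reporting helper used throughout the cluster summaries: `100 * count /
#' total`, rounded. Zero totals give `NA` rather than 0 so that empty
#' clusters are visibly undefined.
#'
#' @param count,total numeric vectors (recycled).
#' @param digits decimal places to round to.
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct(450, 5468, 2) # 8.23
pct <- function(count, total, digits = 1) {
  out <- ifelse(total > 0, 100 * count / total, NA_real_)
  round(out, digits)
}

# Deterministic per-table substream seed derived from one global seed.
# Adding a new table key never perturbs streams of existing tables.
sub_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) + 31))
  as.integer((abs(as.numeric(seed)) * 1103 + h * 7919) %% 2147483629)
}

# Evaluate expr under a temporary RNG state seeded from (seed, key),
# restoring the caller's RNG state afterwards.
with_sub_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, key))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
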