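# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Derive a per-stage random seed from a global seed so pipeline stages can be
## regenerated independently.  Kept strictly below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## Upper-triangle vector of a square matrix, row/col order fixed.
upper_vec <- function(m) m[upper.tri(m)]

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two labelings of the same items, corrected for
#' chance; 1 means identical partitions, 0 is the expectation under random
#' labeling.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

## stop() with sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !lo_ok || !hi_ok)
    abort("%s must be a single value in %s0,1%s", name,
          if (open_left) "(" else "[", if (open_right) ")" else "]")
  invisible(x)
}
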