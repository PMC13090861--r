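# Two-sided rank-sum (Mann-Whitney/Wilcoxon) test.
#
# Exact path: the null distribution of the rank sum is computed over the
# observed multiset of midranks by dynamic programming (counting, for every
# attainable rank sum, the number of size-n_a subsets achieving it), so ties
# are handled exactly. Midranks are half-integers; doubling makes all sums
# integer-valued. Two-sided p = min(1, 2 * min(P(W <= w), P(W >= w))).
#
# Approximate path (either group larger than `exact_max_n`): the standard
# continuity-corrected normal approximation with midranks and tie-corrected
# variance, via stats::wilcox.test(exact = FALSE, correct = TRUE).

#' Two-sided rank-sum test
#'
#' Compares two independent samples with the two-sided rank-sum test.
#' The exact null distribution (enumerated over the observed ranks,
#' midranks for ties) is used whenever the smaller group has at most
#' `exact_max_n` observations; otherwise the continuity-corrected normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max_n Largest minimum group size for which the exact
#'   distribution is enumerated (default 10).
#' @return List with elements `statistic` (rank sum of `x` in the pooled
#'   ranking), `p_value`, and `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exactly
#' @export
ranksum_test <- function(x, y, exact_max_n = 10L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (min(nx, ny) <= exact_max_n) {
    p <- ranksum_exact_p(r, nx)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    p <- ranksum_approx_p(x, y)
    list(statistic = w, p_value = p, method = "normal_approx")
  }
}

# Exact two-sided p for the rank sum of the first nx pooled ranks.
# DP over doubled midranks; enumerates subsets of the smaller group and maps
# back through W_x + W_y = n(n+1)/2.
ranksum_exact_p <- function(r, nx) {
  n <- length(r)
  ny <- n - nx
  r2 <- as.integer(round(2 * r))
  w2x <- sum(r2[seq_len(nx)])
  if (nx <= ny) {
    m <- nx; w2 <- w2x
  } else {
    m <- ny; w2 <- sum(r2) - w2x
  }
  S <- sum(r2)
  # counts[k + 1, s + 1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  counts[1L, 1L] <- 1
  for (ri in r2) {
    for (k in (m - 1L):0) {
      src <- counts[k + 1L, 1:(S + 1L - ri)]
      counts[k + 2L, (ri + 1L):(S + 1L)] <-
        counts[k + 2L, (ri + 1L):(S + 1L)] + src
    }
  }
  dist <- counts[m + 1L, ]
  total <- sum(dist)
  sums <- 0:S
  p_le <- sum(dist[sums <= w2]) / total
  p_ge <- sum(dist[sums >= w2]) / total
  min(1, 2 * min(p_le, p_ge))
}

ranksum_approx_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)  # degenerate: all values tied
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = FALSE, correct = TRUE)
  )
  unname(res$p.value)
}
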