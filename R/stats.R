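#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test on the rank sum of `x` within the pooled sample. For a
#' combined sample size of at most 20 the p-value is exact, computed by a
#' tie-safe counting recursion over all subsets of the pooled (mid-)ranks;
#' for larger samples the normal approximation with tie correction and
#' continuity correction is used. When every pooled value is tied the
#' p-value is 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Combined size up to which the exact branch is used.
#' @return An object of class `htest` with `statistic` (rank sum of `x`),
#'   `p.value` and `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p.value # exact: 0.1
#' @export
rank_sum_test <- function(x, y, exact_max = 20L) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  ranks <- rank(c(x, y))
  w <- sum(ranks[seq_len(nx)])
  if (n <= exact_max) {
    p <- rank_sum_exact_p(ranks, nx, w)
    method <- "Wilcoxon rank sum test (exact enumeration)"
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(ranks)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- w - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Wilcoxon rank sum test (normal approximation, tie-corrected)"
  }
  structure(
    list(
      statistic = c(W = w), p.value = p, method = method,
      data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))
    ),
    class = "htest"
  )
}

# exact two-sided p by dynamic programming: distribution of the sum of nx
# ranks drawn without replacement from the pooled rank multiset. Ranks are
# doubled so midranks from ties stay integral.
rank_sum_exact_p <- function(ranks, nx, w) {
  r2 <- as.integer(round(2 * ranks))
  w2 <- as.integer(round(2 * w))
  total <- sum(r2)
  # counts[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  counts <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (r in r2) {
    for (k in nx:1) { # descend so each element is used at most once
      nonzero <- which(counts[k, ] > 0)
      if (length(nonzero) == 0) next
      counts[k + 1L, nonzero + r] <- counts[k + 1L, nonzero + r] + counts[k, nonzero]
    }
  }
  dist <- counts[nx + 1L, ]
  total_subsets <- sum(dist)
  p_le <- sum(dist[seq_len(w2 + 1L)]) / total_subsets
  p_ge <- sum(dist[(w2 + 1L):length(dist)]) / total_subsets
  min(1, 2 * min(p_le, p_ge))
}

#' Significance stars
#'
#' Stars at the 0.05 / 0.01 / 0.001 levels, as used in the figure
#' annotations.
#'
#' @param p P-value(s).
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
p_stars <- function(p) {
  cut(p,
      breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", ""), right = FALSE) |> as.character()
}
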