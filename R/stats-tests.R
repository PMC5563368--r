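# Shared nonparametric test helpers: Dunn's post hoc z, pooled two-sample
# proportion z, and a Mann-Whitney wrapper with an explicit exactness rule.

#' Dunn's post hoc pairwise comparisons
#'
#' Standard Dunn z statistics on the joint ranking (midranks, tie
#' correction), with Bonferroni adjustment over the pairs. Intended as the
#' follow-up to a Kruskal-Wallis omnibus test.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return data.frame with columns `group1`, `group2`, `z`, `p`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(vals)
  r <- rank(vals)
  meanrank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- tabulate(match(vals, unique(vals)))
  tiecorr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tiecorr) * (1 / n[[a]] + 1 / n[[b]]))
    z[j] <- (meanrank[[a]] - meanrank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adjusted = pmin(1, p * ncol(pairs)), stringsAsFactors = FALSE)
}

#' Two-sample pooled-proportion z-test
#'
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))` with `p` the pooled
#' proportion; two-sided p from the normal distribution. When the pooled
#' proportion is 0 or 1 the statistic is undefined and the result is
#' flagged degenerate.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `estimate1`, `estimate2`, `z`, `p.value`, `degenerate`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stop_if_not(n1 > 0 && n2 > 0 && x1 >= 0 && x2 >= 0 && x1 <= n1 && x2 <= n2,
              "invalid counts")
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool == 0 || pool == 1) {
    return(list(estimate1 = p1, estimate2 = p2, z = NA_real_,
                p.value = NA_real_, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(estimate1 = p1, estimate2 = p2, z = z,
       p.value = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

# Two-sided Mann-Whitney; exact null distribution when the combined sample
# is small and tie-free, normal approximation with continuity correction
# otherwise.
mann_whitney <- function(x, y, exact_max = 20) {
  ex <- (length(x) + length(y)) <= exact_max &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = ex, correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, exact = ex)
}
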