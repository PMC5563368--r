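#' Signed fold change
#'
#' Maps the treated/control ratio `r` to `r` when `r >= 1` and `-1/r`
#' otherwise, so that `|FC| >= 1` always and the sign carries the direction
#' of regulation. A ratio of exactly 1 maps to `+1`.
#'
#' @param treated_mean,control_mean positive mean intensities (vectorized).
#' @return Signed fold change(s).
#' @export
signed_fold_change <- function(treated_mean, control_mean) {
  stop_if_not(all(treated_mean > 0) && all(control_mean > 0),
              "means must be positive")
  r <- treated_mean / control_mean
  ifelse(r >= 1, r, -1 / r)
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] with the degenerate
#' all-identical case mapped to `H = 0, p = 1` (the chi-square machinery is
#' undefined when every observation ties).
#'
#' @param groups list of two or more numeric vectors.
#' @return list with elements `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  stop_if_not(all(vapply(groups, length, 1L) >= 1), "every group must be nonempty")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    return(list(statistic = 0, p.value = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

# Row-wise two-or-more-group Kruskal-Wallis over a matrix. `sizes` gives the
# number of consecutive columns in each group. Used for the genome-scale
# per-stress loop; equality with stats::kruskal.test is asserted in the
# test suite.
kw_rows <- function(x, sizes) {
  n <- sum(sizes)
  stop_if_not(ncol(x) == n, "column count must equal sum of group sizes")
  grp <- rep(seq_along(sizes), sizes)
  H <- numeric(nrow(x))
  p <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    if (length(unique(v)) == 1L) {
      H[i] <- 0; p[i] <- 1
      next
    }
    r <- rank(v)
    Rk <- tapply(r, grp, sum)
    h <- 12 / (n * (n + 1)) * sum(Rk^2 / sizes) - 3 * (n + 1)
    ties <- tabulate(match(v, unique(v)))
    cf <- 1 - sum(ties^3 - ties) / (n^3 - n)
    h <- h / cf
    H[i] <- h
    p[i] <- stats::pchisq(h, df = length(sizes) - 1, lower.tail = FALSE)
  }
  list(statistic = H, p.value = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; returns q-values in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  stop_if_not(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-stress signed fold change and FDR table
#'
#' For every gene and stress, the fold change is computed per timepoint
#' (treated replicate mean over control replicate mean) and the timepoint
#' with the larger `|FC|` is reported. The rank-test p-value compares
#' control against treated replicates; by default the two timepoints are
#' pooled (two groups of `replicates x timepoints` samples), which gives
#' the test enough resolution for genome-wide FDR control at three
#' replicates per cell. q-values are Benjamini-Hochberg adjusted per stress
#' across genes.
#'
#' @param dataset a filtered, normalized `stress_expression`.
#' @param test_grouping `"pooled"` (default; control vs treated pooling
#'   timepoints) or `"per_timepoint"` (control vs treated at the reported
#'   timepoint only).
#' @return A long data.frame of class `fc_table` with columns `gene`,
#'   `stress`, `fc`, `timepoint` (the one reported), `p`, `q`.
#' @export
fold_change_table <- function(dataset, test_grouping = c("pooled", "per_timepoint")) {
  stop_if_not(inherits(dataset, "stress_expression"), "`dataset` must be a stress_expression")
  test_grouping <- match.arg(test_grouping)
  s <- dataset$samples
  stressors <- unique(s$stress)
  timepoints <- unique(s$timepoint)
  genes <- rownames(dataset$intensities)
  out <- vector("list", length(stressors))
  for (k in seq_along(stressors)) {
    st <- stressors[k]
    fc_tp <- matrix(NA_real_, length(genes), length(timepoints))
    p_tp <- matrix(NA_real_, length(genes), length(timepoints))
    for (j in seq_along(timepoints)) {
      tp <- timepoints[j]
      ic <- sample_index(dataset, st, "control", tp)
      it <- sample_index(dataset, st, "treated", tp)
      if (length(ic) == 0L) {
        stop("no control samples for stress '", st, "' at timepoint '", tp, "'",
             call. = FALSE)
      }
      stop_if_not(length(ic) >= 2 && length(it) >= 2,
                  "need >= 2 replicates per (stress, timepoint, condition)")
      cm <- rowMeans(dataset$intensities[, ic, drop = FALSE])
      tm <- rowMeans(dataset$intensities[, it, drop = FALSE])
      fc_tp[, j] <- signed_fold_change(tm, cm)
      if (test_grouping == "per_timepoint") {
        kw <- kw_rows(dataset$intensities[, c(ic, it), drop = FALSE],
                      c(length(ic), length(it)))
        p_tp[, j] <- kw$p.value
      }
    }
    best <- max.col(abs(fc_tp), ties.method = "first")
    fc <- fc_tp[cbind(seq_along(genes), best)]
    if (test_grouping == "pooled") {
      ic <- sample_index(dataset, st, "control")
      it <- sample_index(dataset, st, "treated")
      kw <- kw_rows(dataset$intensities[, c(ic, it), drop = FALSE],
                    c(length(ic), length(it)))
      p <- kw$p.value
    } else {
      p <- p_tp[cbind(seq_along(genes), best)]
    }
    out[[k]] <- data.frame(gene = genes, stress = st, fc = fc,
                           timepoint = timepoints[best], p = p,
                           q = bh_fdr(p), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "stressors") <- stressors
  class(res) <- c("fc_table", "data.frame")
  res
}

# Long fc_table -> named matrices (genes x stressors) for fc and q.
fc_matrices <- function(fc_table) {
  stressors <- attr(fc_table, "stressors") %||% unique(fc_table$stress)
  genes <- unique(fc_table$gene)
  fc <- q <- matrix(NA_real_, length(genes), length(stressors),
                    dimnames = list(genes, stressors))
  gi <- match(fc_table$gene, genes)
  si <- match(fc_table$stress, stressors)
  fc[cbind(gi, si)] <- fc_table$fc
  q[cbind(gi, si)] <- fc_table$q
  list(fc = fc, q = q)
}
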