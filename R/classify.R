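#' Classify genes by multi-stress expression pattern
#'
#' Assigns each gene to one of the pattern classes used throughout the
#' package:
#' \describe{
#'   \item{GSR_up}{general stress response: `FC >= deg` under every stress,
#'     each call passing the FDR gate.}
#'   \item{generally_down}{`FC <= -deg` under every stress, each passing FDR.}
#'   \item{unique_up / unique_down}{`|FC| >= deg` (FDR-gated) under exactly
#'     one stress and `|FC| <= unique_other` under all the others.}
#'   \item{background}{`|FC| <= background` under every stress.}
#'   \item{low_regulated}{`background < FC < deg` under every stress.}
#'   \item{unclassified}{everything else.}
#' }
#' DEG flags (up/down per stress) require `|FC| >= deg` and `q <
#' fdr_cutoff`. The FDR gate applies to DEG/GSR/unique calls but not to the
#' background and low-regulated classes, which are defined by FC bounds
#' alone. Class predicates are mutually exclusive by construction; this is
#' asserted.
#'
#' @param fc_table an `fc_table` from [fold_change_table()] (or any long
#'   data.frame with `gene`, `stress`, `fc`, `q`).
#' @param thresholds list with elements `deg` (default 2), `unique_other`
#'   (1.4) and `background` (1.2).
#' @param fdr_cutoff FDR gate for DEG calls; default 0.05.
#' @return data.frame of class `gene_classification` with columns `gene`,
#'   `class`, `stress` (the stressor for unique classes, `NA` otherwise).
#'   DEG up/down flag matrices are attached as attributes `deg_up` and
#'   `deg_down`.
#' @export
classify_genes <- function(fc_table,
                           thresholds = list(deg = 2, unique_other = 1.4, background = 1.2),
                           fdr_cutoff = 0.05) {
  stop_if_not(all(c("deg", "unique_other", "background") %in% names(thresholds)),
              "thresholds must name deg, unique_other, background")
  th <- thresholds
  stop_if_not(th$deg > th$unique_other && th$unique_other > th$background && th$background > 1,
              "threshold ordering deg > unique_other > background > 1 violated")
  m <- fc_matrices(fc_table)
  fc <- m$fc; q <- m$q
  stop_if_not(!anyNA(fc) && !anyNA(q), "fc table must cover every gene x stress cell")
  sig <- q < fdr_cutoff
  deg_up <- fc >= th$deg & sig
  deg_down <- fc <= -th$deg & sig

  gsr_up <- rowSums(deg_up) == ncol(fc)
  gen_down <- rowSums(deg_down) == ncol(fc)
  background <- rowSums(abs(fc) <= th$background) == ncol(fc)
  low_reg <- rowSums(fc > th$background & fc < th$deg) == ncol(fc)

  # unique classes require at least one *other* stress to bound
  if (ncol(fc) >= 2) {
    n_small <- rowSums(abs(fc) <= th$unique_other)
    one_big <- rowSums(abs(fc) >= th$deg) == 1L
    uniq_up <- deg_up & (n_small == ncol(fc) - 1L) & one_big
    uniq_down <- deg_down & (n_small == ncol(fc) - 1L) & one_big
  } else {
    uniq_up <- uniq_down <- matrix(FALSE, nrow(fc), ncol(fc), dimnames = dimnames(fc))
  }
  is_uniq_up <- rowSums(uniq_up) == 1L
  is_uniq_down <- rowSums(uniq_down) == 1L

  hits <- cbind(gsr_up, gen_down, is_uniq_up, is_uniq_down, background, low_reg)
  stopifnot(all(rowSums(hits) <= 1L))  # predicates are mutually exclusive

  cls <- rep("unclassified", nrow(fc))
  cls[background] <- "background"
  cls[low_reg] <- "low_regulated"
  cls[gsr_up] <- "GSR_up"
  cls[gen_down] <- "generally_down"
  cls[is_uniq_up] <- "unique_up"
  cls[is_uniq_down] <- "unique_down"
  stress <- rep(NA_character_, nrow(fc))
  stress[is_uniq_up] <- colnames(fc)[max.col(uniq_up, "first")[is_uniq_up]]
  stress[is_uniq_down] <- colnames(fc)[max.col(uniq_down, "first")[is_uniq_down]]

  out <- data.frame(gene = rownames(fc), class = cls, stress = stress,
                    stringsAsFactors = FALSE)
  attr(out, "deg_up") <- deg_up
  attr(out, "deg_down") <- deg_down
  attr(out, "stressors") <- colnames(fc)
  class(out) <- c("gene_classification", "data.frame")
  out
}

#' @export
print.gene_classification <- function(x, ...) {
  cat("gene_classification:", nrow(x), "genes\n")
  print(table(x$class))
  invisible(x)
}

#' Per-stress and global class count summary
#'
#' Produces the standard summary table: one row per stress with DEG,
#' up/down and uniquely-regulated counts, a non-redundant `Sum` row, and
#' the global class counts (generally regulated / up / down, background,
#' low-regulated) repeated on every row, mirroring the conventional layout
#' of multi-stress DEG tables.
#'
#' @param classification a `gene_classification`.
#' @return data.frame of class `class_summary` with columns `stress`,
#'   `degs`, `up`, `down`, `uniquely_regulated`, `uniquely_up`,
#'   `uniquely_down`, `generally_regulated`, `generally_up`,
#'   `generally_down`, `background`, `low_regulated`. The last row is the
#'   non-redundant sum.
#' @export
summarize_classes <- function(classification) {
  stop_if_not(inherits(classification, "gene_classification"),
              "`classification` must come from classify_genes()")
  deg_up <- attr(classification, "deg_up")
  deg_down <- attr(classification, "deg_down")
  stressors <- attr(classification, "stressors")
  n_gsr <- sum(classification$class == "GSR_up")
  n_gdown <- sum(classification$class == "generally_down")
  n_bg <- sum(classification$class == "background")
  n_low <- sum(classification$class == "low_regulated")
  rows <- lapply(stressors, function(st) {
    uu <- sum(classification$class == "unique_up" & classification$stress == st, na.rm = TRUE)
    ud <- sum(classification$class == "unique_down" & classification$stress == st, na.rm = TRUE)
    data.frame(stress = st,
               degs = sum(deg_up[, st] | deg_down[, st]),
               up = sum(deg_up[, st]),
               down = sum(deg_down[, st]),
               uniquely_regulated = uu + ud,
               uniquely_up = uu,
               uniquely_down = ud,
               generally_regulated = n_gsr + n_gdown,
               generally_up = n_gsr,
               generally_down = n_gdown,
               background = n_bg,
               low_regulated = n_low,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  sum_row <- data.frame(stress = "Sum (non-redundant)",
                        degs = sum(rowSums(deg_up | deg_down) > 0),
                        up = sum(rowSums(deg_up) > 0),
                        down = sum(rowSums(deg_down) > 0),
                        uniquely_regulated = sum(tab$uniquely_regulated),
                        uniquely_up = sum(tab$uniquely_up),
                        uniquely_down = sum(tab$uniquely_down),
                        generally_regulated = n_gsr + n_gdown,
                        generally_up = n_gsr,
                        generally_down = n_gdown,
                        background = n_bg,
                        low_regulated = n_low,
                        stringsAsFactors = FALSE)
  out <- rbind(tab, sum_row)
  # internal consistency invariants
  stopifnot(all(out$degs[seq_along(stressors)] ==
                  out$up[seq_along(stressors)] + out$down[seq_along(stressors)]),
            all(out$uniquely_regulated == out$uniquely_up + out$uniquely_down),
            out$uniquely_up[nrow(out)] == sum(tab$uniquely_up),
            all(out$generally_regulated == out$generally_up + out$generally_down))
  class(out) <- c("class_summary", "data.frame")
  out
}

#' Non-redundant totals from a transcribed per-stress count table
#'
#' Given per-stress counts (one row per stressor) this recomputes the
#' arithmetic identities a consistent summary table must satisfy: the
#' non-redundant uniquely-up / uniquely-down / uniquely-regulated totals
#' (unique classes are disjoint across stresses, so the total is the column
#' sum), per-row `degs = up + down` checks, and `generally_regulated =
#' generally_up + generally_down`.
#'
#' @param counts data.frame with columns `stress`, `degs`, `up`, `down`,
#'   `uniquely_up`, `uniquely_down` and optionally `uniquely_regulated`,
#'   `generally_up`, `generally_down`.
#' @return list with `uniquely_up_total`, `uniquely_down_total`,
#'   `uniquely_regulated_total` (sum of the printed uniquely-regulated
#'   column when present, else up+down), `generally_regulated` (when the
#'   global columns are present) and logical vector `degs_consistent`
#'   flagging rows where `degs == up + down`.
#' @export
class_count_totals <- function(counts) {
  req <- c("stress", "degs", "up", "down", "uniquely_up", "uniquely_down")
  stop_if_not(all(req %in% names(counts)),
              paste("counts must contain columns:", paste(req, collapse = ", ")))
  ur <- if ("uniquely_regulated" %in% names(counts)) counts$uniquely_regulated
        else counts$uniquely_up + counts$uniquely_down
  out <- list(
    uniquely_up_total = sum(counts$uniquely_up),
    uniquely_down_total = sum(counts$uniquely_down),
    uniquely_regulated_total = sum(ur),
    degs_consistent = counts$degs == counts$up + counts$down
  )
  if (all(c("generally_up", "generally_down") %in% names(counts))) {
    out$generally_regulated <- unique(counts$generally_up) + unique(counts$generally_down)
  }
  out
}

#' Compare basal expression across gene classes
#'
#' Basal level is the mean control intensity per gene. Classes are compared
#' with a Kruskal-Wallis omnibus test followed by Dunn's post hoc pairwise
#' comparisons (Bonferroni adjusted). Classes with fewer than two genes are
#' excluded with a warning; with a single usable class only descriptive
#' output is returned.
#'
#' @param dataset the `stress_expression` used for classification.
#' @param classification a `gene_classification`.
#' @param classes which class labels to compare; defaults to the three
#'   classes whose basal levels are of scientific interest.
#' @return list with `basal` (named list of per-gene basal means by class),
#'   `medians`, `kruskal` (omnibus, or NULL), `dunn` (pairwise data.frame,
#'   or NULL).
#' @export
compare_basal_expression <- function(dataset, classification,
                                     classes = c("GSR_up", "low_regulated", "background")) {
  stop_if_not(inherits(dataset, "stress_expression"), "`dataset` must be a stress_expression")
  ctrl <- which(dataset$samples$condition == "control")
  basal_all <- rowMeans(dataset$intensities[, ctrl, drop = FALSE])
  groups <- list()
  for (cl in classes) {
    g <- classification$gene[classification$class == cl]
    g <- intersect(g, names(basal_all))
    if (length(g) < 2) {
      warning("class '", cl, "' has < 2 genes with expression data; excluded", call. = FALSE)
      next
    }
    groups[[cl]] <- basal_all[g]
  }
  out <- list(basal = groups, medians = vapply(groups, stats::median, 1.0),
              kruskal = NULL, dunn = NULL)
  if (length(groups) >= 2) {
    out$kruskal <- kruskal_wallis(groups)
    out$dunn <- dunn_posthoc(groups)
  }
  out
}
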