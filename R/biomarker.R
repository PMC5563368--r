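# Delta-delta-Ct quantification and the two-stage biomarker specificity
# screen (unique single-stress induction, retained specificity under
# combined leave-one-out stress panels).

# Mean Ct for one (gene, sample), averaging technical replicates.
mean_ct <- function(ct, gene, sample) {
  v <- ct$ct[ct$gene_id == gene & ct$sample_id == sample]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Fold change by the comparative Ct method
#'
#' `dCt = Ct_gene - Ct_reference` within each sample; `ddCt =
#' dCt_treated - dCt_control`; `fold = 2^(-ddCt)` (amplification
#' efficiency fixed at 2). Technical replicate Ct values are averaged
#' before the subtraction.
#'
#' @param ct data.frame with columns `gene_id`, `sample_id`, `ct`.
#' @param gene target gene id.
#' @param treated_sample,control_sample sample ids.
#' @param reference_gene internal control gene id (must be measured in
#'   both samples).
#' @return fold change (positive real).
#' @export
ddct_fold_change <- function(ct, gene, treated_sample, control_sample,
                             reference_gene) {
  rt <- mean_ct(ct, reference_gene, treated_sample)
  rc <- mean_ct(ct, reference_gene, control_sample)
  if (is.na(rt) || is.na(rc)) {
    stop("reference gene '", reference_gene, "' missing from a sample", call. = FALSE)
  }
  gt <- mean_ct(ct, gene, treated_sample)
  gcx <- mean_ct(ct, gene, control_sample)
  if (is.na(gt) || is.na(gcx)) {
    stop("gene '", gene, "' not measured in both samples", call. = FALSE)
  }
  ddct <- (gt - rt) - (gcx - rc)
  2^(-ddct)
}

#' Single-stress uniqueness screen for biomarker candidates
#'
#' Candidates are genes induced at least `up_threshold`-fold under exactly
#' one non-excluded stressor while staying within `other_threshold` under
#' every other stressor. Stressors in `exclude_stressors` cannot nominate
#' candidates (e.g. treatments at unrealistic field concentrations), but
#' still count as "other" stressors for the specificity bound.
#'
#' @param folds matrix or data.frame of fold inductions, genes in rows
#'   (rownames = gene ids), stressors in columns.
#' @param exclude_stressors stress labels that cannot nominate candidates.
#' @param up_threshold minimum induction under the target stress; default 2.
#' @param other_threshold maximum |fold| under all other stresses;
#'   default 1.4. Folds below 1 are compared on the reciprocal scale.
#' @return data.frame with `gene` and `target_stress` for each candidate.
#' @export
uniqueness_screen <- function(folds, exclude_stressors = character(0),
                              up_threshold = 2, other_threshold = 1.4) {
  folds <- as.matrix(folds)
  stop_if_not(!is.null(rownames(folds)) && !is.null(colnames(folds)),
              "folds need gene rownames and stressor colnames")
  mag <- ifelse(folds >= 1, folds, 1 / folds)  # |FC| on the symmetric scale
  out <- list()
  for (g in rownames(folds)) {
    up <- which(folds[g, ] >= up_threshold)
    if (length(up) != 1L) next
    st <- colnames(folds)[up]
    if (any(mag[g, -up] > other_threshold)) next
    if (st %in% exclude_stressors) next
    out[[length(out) + 1L]] <- data.frame(gene = g, target_stress = st,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), target_stress = character(0)))
  }
  do.call(rbind, out)
}

#' Combined-panel specificity validation of biomarker candidates
#'
#' A candidate is `validated` when (i) its fold induction reaches
#' `induced_threshold` in every panel containing its target stressor and
#' (ii) the specificity ratio — minimum induction over panels containing
#' the target divided by maximum induction over panels lacking it — is at
#' least `specificity_ratio_min`. A target present in all panels cannot be
#' assessed and is flagged.
#'
#' @param candidates data.frame from [uniqueness_screen()] (`gene`,
#'   `target_stress`).
#' @param panel_folds matrix/data.frame of fold inductions, genes in rows,
#'   panels in columns.
#' @param panel_composition named list: panel -> character vector of
#'   stressors applied.
#' @param induced_threshold minimum fold in target-containing panels;
#'   default 2.
#' @param specificity_ratio_min minimum specificity ratio; default 2.
#' @return data.frame of class `biomarker_report`: `gene`,
#'   `target_stress`, `min_with_target`, `max_without_target`,
#'   `specificity_ratio`, `verdict` (`"validated"`/`"rejected"`/
#'   `"unassessable"`).
#' @export
validate_biomarkers <- function(candidates, panel_folds, panel_composition,
                                induced_threshold = 2, specificity_ratio_min = 2) {
  panel_folds <- as.matrix(panel_folds)
  panels <- colnames(panel_folds)
  stop_if_not(all(panels %in% names(panel_composition)),
              "every panel column needs a composition entry")
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    g <- candidates$gene[i]; st <- candidates$target_stress[i]
    stop_if_not(g %in% rownames(panel_folds),
                paste0("candidate '", g, "' not measured in the panels"))
    with_t <- panels[vapply(panel_composition[panels], function(p) st %in% p, TRUE)]
    without_t <- setdiff(panels, with_t)
    if (length(without_t) == 0) {
      return(data.frame(gene = g, target_stress = st, min_with_target = NA_real_,
                        max_without_target = NA_real_, specificity_ratio = NA_real_,
                        verdict = "unassessable", stringsAsFactors = FALSE))
    }
    mn <- min(panel_folds[g, with_t])
    mx <- max(panel_folds[g, without_t])
    ratio <- mn / mx
    ok <- mn >= induced_threshold && ratio >= specificity_ratio_min
    data.frame(gene = g, target_stress = st, min_with_target = mn,
               max_without_target = mx, specificity_ratio = ratio,
               verdict = if (ok) "validated" else "rejected",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(gene = character(0), target_stress = character(0),
                         min_with_target = numeric(0), max_without_target = numeric(0),
                         specificity_ratio = numeric(0), verdict = character(0))
  class(out) <- c("biomarker_report", "data.frame")
  out
}

#' Fold inductions per gene and panel from a Ct table
#'
#' Applies [ddct_fold_change()] to every (gene, treated panel) pair
#' against the shared control sample.
#'
#' @param ct_data list as produced by [simulate_ct_table()]: elements
#'   `ct`, `samples`, `reference_gene`.
#' @return matrix of folds, genes in rows, panels in columns.
#' @export
panel_fold_matrix <- function(ct_data) {
  samples <- ct_data$samples
  ctrl <- samples$sample_id[samples$condition == "control"]
  stop_if_not(length(ctrl) == 1, "expected exactly one control sample")
  treated <- samples[samples$condition == "treated", ]
  genes <- setdiff(unique(ct_data$ct$gene_id), ct_data$reference_gene)
  m <- matrix(NA_real_, length(genes), nrow(treated),
              dimnames = list(genes, treated$panel))
  for (g in genes) {
    for (j in seq_len(nrow(treated))) {
      m[g, j] <- ddct_fold_change(ct_data$ct, g, treated$sample_id[j], ctrl,
                                  ct_data$reference_gene)
    }
  }
  m
}
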