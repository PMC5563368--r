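#' Default stressor panel
#'
#' The eight rhizotoxic treatments emulated by the synthetic generator: six
#' metal/metalloid ions and two allelochemicals.
#'
#' @return character vector of stress labels.
#' @export
default_stressors <- function() c("Cu", "AsV", "Cd", "Hg", "Cr", "V", "FA", "juglone")

#' Configuration for the synthetic expression generator
#'
#' Captures the emulated study design: a shared gene universe measured
#' under each stressor at two timepoints with replicated control and
#' treated arrays, plus the planted ground-truth classes.
#'
#' @param n_genes total genes in the universe.
#' @param stressors stress labels; default [default_stressors()].
#' @param timepoints timepoint labels; default `c("1h", "3h")`.
#' @param replicates biological replicates per (stress, timepoint,
#'   condition); default 3, minimum 2.
#' @param planted_counts named list of planted class sizes: `gsr_up`,
#'   `generally_down`, `unique_up` and `unique_down` (per stress),
#'   `background`, `low_regulated`. Remaining genes are filler.
#' @param noise_sd standard deviation of log2-intensity noise; default 0.05.
#' @param baseline_intensity geometric centre of baseline intensities;
#'   default 1000.
#' @param background_basal_boost multiplicative boost applied to background
#'   genes' baselines (background genes in real data sit high and flat);
#'   default 4.
#' @param filler_active_fraction fraction of filler genes that respond (with
#'   `|FC| >= 2`) in several-but-not-all stresses, so per-stress DEG counts
#'   have a realistic scale; default 0.3.
#' @param seed master seed; all substreams derive from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 2000,
                             stressors = default_stressors(),
                             timepoints = c("1h", "3h"),
                             replicates = 3,
                             planted_counts = list(gsr_up = 100, generally_down = 20,
                                                   unique_up = 10, unique_down = 0,
                                                   background = 100, low_regulated = 50),
                             noise_sd = 0.05,
                             baseline_intensity = 1000,
                             background_basal_boost = 4,
                             filler_active_fraction = 0.3,
                             seed = 1) {
  pc <- utils::modifyList(list(gsr_up = 0, generally_down = 0, unique_up = 0,
                               unique_down = 0, background = 0, low_regulated = 0),
                          planted_counts)
  stop_if_not(all(unlist(pc) >= 0), "planted counts must be >= 0")
  stop_if_not(replicates >= 2, "replicates must be >= 2")
  stop_if_not(noise_sd >= 0, "noise_sd must be non-negative")
  stop_if_not(baseline_intensity > 0, "baseline_intensity must be positive")
  n_planted <- pc$gsr_up + pc$generally_down + pc$background + pc$low_regulated +
    (pc$unique_up + pc$unique_down) * length(stressors)
  if (n_planted > n_genes) {
    stop("planted counts (", n_planted, ") exceed n_genes (", n_genes, ")", call. = FALSE)
  }
  structure(list(n_genes = n_genes, stressors = stressors, timepoints = timepoints,
                 replicates = replicates, planted_counts = pc, noise_sd = noise_sd,
                 baseline_intensity = baseline_intensity,
                 background_basal_boost = background_basal_boost,
                 filler_active_fraction = filler_active_fraction, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic multi-stress expression dataset with ground truth
#'
#' Intensities are log-normal around a per-gene baseline with
#' multiplicative treatment effects, so fold changes on replicate means
#' recover the planted effects exactly in the noise-free limit. Planted
#' effects are applied at both timepoints. Effect sizes are drawn per gene
#' and stress: 2.5-8x for GSR/unique/generally-down genes (a margin above
#' the 2x class boundary), 1.4-1.8x for low-regulated genes, `|log2 FC| <=
#' 0.1` for background genes. A configurable fraction of filler genes
#' responds in 2-7 stresses (never satisfying any planted-class predicate),
#' giving per-stress DEG fractions of a realistic scale; the remaining
#' fillers are quiet with one mild 1.3x response.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a [stress_expression()]) and `truth`, a
#'   data.frame with `gene`, `class` (one of `GSR_up`, `generally_down`,
#'   `unique_up`, `unique_down`, `background`, `low_regulated`, `filler`)
#'   and `stress` (for unique classes). The planted log2 fold-change matrix
#'   is attached as attribute `"true_log2fc"`.
#' @export
simulate_expression <- function(config) {
  stop_if_not(inherits(config, "synthetic_config"), "`config` must be a synthetic_config")
  with_seed(substream_seed(config$seed, "expression"), {
    ng <- config$n_genes
    st <- config$stressors
    ns <- length(st)
    genes <- sprintf("g%05d", seq_len(ng))
    pc <- config$planted_counts

    cls <- rep("filler", ng)
    stress_of <- rep(NA_character_, ng)
    at <- 0
    take <- function(n) {
      idx <- at + seq_len(n); at <<- at + n; idx
    }
    i_gsr <- take(pc$gsr_up);          cls[i_gsr] <- "GSR_up"
    i_gd <- take(pc$generally_down);   cls[i_gd] <- "generally_down"
    for (s in st) {
      iu <- take(pc$unique_up); cls[iu] <- "unique_up"; stress_of[iu] <- s
      id <- take(pc$unique_down); cls[id] <- "unique_down"; stress_of[id] <- s
    }
    i_bg <- take(pc$background);       cls[i_bg] <- "background"
    i_low <- take(pc$low_regulated);   cls[i_low] <- "low_regulated"
    i_fill <- which(cls == "filler")

    # planted log2 effects (genes x stressors)
    lfc <- matrix(0, ng, ns, dimnames = list(genes, st))
    big <- function(n) stats::runif(n, log2(2.5), log2(8))
    lfc[i_gsr, ] <- big(length(i_gsr) * ns)
    lfc[i_gd, ] <- -big(length(i_gd) * ns)
    for (i in which(cls %in% c("unique_up", "unique_down"))) {
      sgn <- if (cls[i] == "unique_up") 1 else -1
      lfc[i, stress_of[i]] <- sgn * big(1)
    }
    lfc[i_bg, ] <- stats::runif(length(i_bg) * ns, -0.1, 0.1)
    lfc[i_low, ] <- stats::runif(length(i_low) * ns, log2(1.4), log2(1.8))
    if (length(i_fill)) {
      active <- i_fill[stats::runif(length(i_fill)) < config$filler_active_fraction]
      quiet <- setdiff(i_fill, active)
      for (i in active) {
        k <- sample(2:min(7, max(2, ns - 1)), 1)
        which_s <- sample(ns, k)
        lfc[i, which_s] <- sample(c(-1, 1), k, replace = TRUE) *
          stats::runif(k, log2(2.3), log2(8))
      }
      for (i in quiet) lfc[i, sample(ns, 1)] <- log2(1.3)
    }

    # baselines (log2); background genes sit higher and flat
    base <- log2(config$baseline_intensity) + stats::runif(ng, -1.7, 3)
    base[i_bg] <- base[i_bg] + log2(config$background_basal_boost)

    samples <- expand.grid(replicate = seq_len(config$replicates),
                           condition = c("control", "treated"),
                           timepoint = config$timepoints,
                           stress = st,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples <- samples[, c("stress", "timepoint", "condition", "replicate")]
    samples$sample_id <- sprintf("%s_%s_%s_r%d", samples$stress, samples$timepoint,
                                 substr(samples$condition, 1, 4), samples$replicate)
    mat <- matrix(NA_real_, ng, nrow(samples), dimnames = list(genes, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base
      if (samples$condition[j] == "treated") mu <- mu + lfc[, samples$stress[j]]
      eps <- if (config$noise_sd > 0) stats::rnorm(ng, 0, config$noise_sd) else 0
      mat[, j] <- 2^(mu + eps)
    }
    truth <- data.frame(gene = genes, class = cls, stress = stress_of,
                        stringsAsFactors = FALSE)
    attr(truth, "true_log2fc") <- lfc
    list(dataset = stress_expression(mat, samples[, c("sample_id", "stress", "timepoint",
                                                      "replicate", "condition")]),
         truth = truth)
  })
}

#' Fraction of planted class labels recovered by the classifier
#'
#' Convenience wrapper: runs filtering, fold-change computation and
#' classification on a generated dataset and compares the assigned labels
#' of planted (non-filler) genes against the truth table. Unique classes
#' must also recover the correct stressor.
#'
#' @param sim output of [simulate_expression()].
#' @param fdr_cutoff FDR gate passed to [classify_genes()].
#' @return list with `recovery` (fraction in `[0, 1]`), `n_planted`, and the
#'   `classification`.
#' @export
classifier_recovery <- function(sim, fdr_cutoff = 0.05) {
  ds <- filter_low_intensity(sim$dataset, 100)
  fc <- fold_change_table(ds)
  cl <- classify_genes(fc, fdr_cutoff = fdr_cutoff)
  truth <- sim$truth[sim$truth$class != "filler", ]
  got <- cl[match(truth$gene, cl$gene), ]
  ok <- !is.na(got$class) & got$class == truth$class &
    (is.na(truth$stress) | (!is.na(got$stress) & got$stress == truth$stress))
  list(recovery = mean(ok), n_planted = nrow(truth), classification = cl)
}
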