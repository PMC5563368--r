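#' Multi-stress expression dataset
#'
#' Lightweight container pairing a positive intensity matrix (genes x
#' samples, arbitrary fluorescence units) with its sample metadata. This is
#' the raw material for fold-change computation and rank testing.
#'
#' @param intensities numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be positive.
#' @param samples data.frame with one row per column of `intensities` and
#'   columns `sample_id`, `stress`, `timepoint`, `replicate`,
#'   `condition` (`"control"` or `"treated"`).
#' @return An object of class `stress_expression`.
#' @export
stress_expression <- function(intensities, samples) {
  stop_if_not(is.matrix(intensities) && is.numeric(intensities),
              "`intensities` must be a numeric matrix")
  stop_if_not(!is.null(rownames(intensities)) || nrow(intensities) == 0,
              "intensity matrix needs gene ids as rownames")
  stop_if_not(!anyDuplicated(rownames(intensities)), "gene ids must be unique")
  stop_if_not(all(intensities > 0), "all intensities must be positive")
  req <- c("sample_id", "stress", "timepoint", "replicate", "condition")
  stop_if_not(all(req %in% names(samples)),
              paste("`samples` must contain columns:", paste(req, collapse = ", ")))
  stop_if_not(nrow(samples) == ncol(intensities),
              "one metadata row per intensity column required")
  stop_if_not(identical(as.character(samples$sample_id), colnames(intensities)),
              "metadata sample_id order must match intensity column order")
  stop_if_not(all(samples$condition %in% c("control", "treated")),
              "condition must be 'control' or 'treated'")
  structure(list(intensities = intensities, samples = as.data.frame(samples)),
            class = "stress_expression")
}

#' @export
print.stress_expression <- function(x, ...) {
  cat("stress_expression:", nrow(x$intensities), "genes x",
      ncol(x$intensities), "samples\n")
  cat("  stressors: ", paste(unique(x$samples$stress), collapse = ", "), "\n", sep = "")
  cat("  timepoints:", paste(unique(x$samples$timepoint), collapse = ", "),
      " replicates:", max(x$samples$replicate), "\n")
  invisible(x)
}

#' @export
dim.stress_expression <- function(x) dim(x$intensities)

# Column indices for a (stress, condition[, timepoint]) cell.
sample_index <- function(dataset, stress, condition, timepoint = NULL) {
  s <- dataset$samples
  idx <- s$stress == stress & s$condition == condition
  if (!is.null(timepoint)) idx <- idx & s$timepoint == timepoint
  which(idx)
}

#' Joint quantile normalization across datasets
#'
#' Forces every sample column onto an identical marginal distribution (the
#' mean of the sorted columns), the standard surrogate for normalizing
#' several array batches together. Gene and sample order are preserved.
#'
#' @param datasets a single `stress_expression` or a list of them sharing a
#'   gene universe.
#' @return The same shape as the input (single object or list) with
#'   normalized intensities.
#' @export
quantile_normalize_joint <- function(datasets) {
  single <- inherits(datasets, "stress_expression")
  if (single) datasets <- list(datasets)
  stop_if_not(length(datasets) >= 1, "need at least one dataset")
  genes <- rownames(datasets[[1]]$intensities)
  for (d in datasets) {
    missing <- setdiff(genes, rownames(d$intensities))
    extra <- setdiff(rownames(d$intensities), genes)
    if (length(missing) || length(extra)) {
      stop("datasets do not share a gene universe; missing ids: ",
           paste(utils::head(c(missing, extra), 5), collapse = ", "), call. = FALSE)
    }
  }
  big <- do.call(cbind, lapply(datasets, function(d) d$intensities[genes, , drop = FALSE]))
  norm <- limma::normalizeQuantiles(big)
  dimnames(norm) <- dimnames(big)
  out <- vector("list", length(datasets))
  at <- 0
  for (i in seq_along(datasets)) {
    nc <- ncol(datasets[[i]]$intensities)
    m <- norm[, at + seq_len(nc), drop = FALSE]
    at <- at + nc
    out[[i]] <- stress_expression(m, datasets[[i]]$samples)
  }
  if (single) out[[1]] else out
}

#' Drop genes below the detection threshold
#'
#' A gene is retained if its intensity reaches `threshold` in at least one
#' sample (max-across-samples rule), so genes silenced in control but
#' induced by stress are kept.
#'
#' @param dataset a `stress_expression`.
#' @param threshold minimum signal intensity; default 100.
#' @return Filtered `stress_expression`; the number of dropped genes is
#'   reported via `message()` and stored in attribute `"n_dropped"`.
#' @export
filter_low_intensity <- function(dataset, threshold = 100) {
  stop_if_not(inherits(dataset, "stress_expression"), "`dataset` must be a stress_expression")
  keep <- apply(dataset$intensities, 1L, max) >= threshold
  n_drop <- sum(!keep)
  if (n_drop > 0) message("filter_low_intensity: dropped ", n_drop, " gene(s) below ", threshold)
  if (!any(keep)) {
    warning("intensity filter removed every gene", call. = FALSE)
  }
  out <- stress_expression(dataset$intensities[keep, , drop = FALSE], dataset$samples)
  attr(out, "n_dropped") <- n_drop
  out
}
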