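#' Parse gene models and derive intron architecture from GFF3
#'
#' Reads a GFF3 file (1-based inclusive coordinates) with gene/mRNA/exon
#' features linked by `Parent` attributes. One representative transcript is
#' used per gene: the first mRNA child in file order. Introns are the gaps
#' between consecutive exons (`length = next_start - prev_end - 1`). Exons
#' without a parent are skipped with a warning; models with overlapping
#' exons are rejected with a warning.
#'
#' @param gff3 path to a GFF3 file, or a character vector of GFF3 lines.
#' @return data.frame of class `gene_models` with columns `gene`, `strand`,
#'   `exon_count`, `intron_count`, `total_intron_length` and list-column
#'   `intron_lengths`.
#' @export
read_gene_models <- function(gff3) {
  path <- gff3
  if (length(gff3) > 1L || grepl("\n", gff3[1]) || grepl("\t", gff3[1])) {
    path <- tempfile(fileext = ".gff3")
    writeLines(gff3, path)
    on.exit(unlink(path), add = TRUE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  get_id <- function(x) as.character(x$ID)
  first_parent <- function(x) {
    p <- x$Parent
    vapply(seq_along(p), function(i) {
      v <- p[[i]]
      if (length(v) == 0) NA_character_ else as.character(v[1])
    }, "")
  }
  genes <- gr[type == "gene"]
  mrnas <- gr[type == "mRNA"]
  exons <- gr[type == "exon"]
  mrna_parent <- first_parent(mrnas)
  exon_parent <- first_parent(exons)
  orphan <- is.na(exon_parent)
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without a Parent attribute skipped", call. = FALSE)
    exons <- exons[!orphan]
    exon_parent <- exon_parent[!orphan]
  }
  out <- list()
  for (i in seq_along(genes)) {
    gid <- get_id(genes[i])
    mi <- which(mrna_parent == gid)
    if (length(mi) == 0) next
    mid <- get_id(mrnas[mi[1]])  # representative transcript: first in file order
    ex <- exons[exon_parent == mid]
    if (length(ex) == 0) next
    st <- sort(GenomicRanges::start(ex))
    en <- GenomicRanges::end(ex)[order(GenomicRanges::start(ex))]
    if (length(st) > 1 && any(st[-1] <= en[-length(en)])) {
      warning("gene '", gid, "' has overlapping exons; model rejected", call. = FALSE)
      next
    }
    introns <- if (length(st) > 1) st[-1] - en[-length(en)] - 1L else integer(0)
    out[[length(out) + 1L]] <- data.frame(
      gene = gid,
      strand = as.character(GenomicRanges::strand(genes[i])),
      exon_count = length(st),
      intron_count = length(introns),
      total_intron_length = sum(introns),
      stringsAsFactors = FALSE)
    out[[length(out)]]$intron_lengths <- list(as.integer(introns))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(0), strand = character(0),
                      exon_count = integer(0), intron_count = integer(0),
                      total_intron_length = integer(0))
    res$intron_lengths <- list()
  }
  class(res) <- c("gene_models", "data.frame")
  res
}

#' Two-sample z-test on intronless fractions
#'
#' Compares the proportion of intronless genes (single-exon models)
#' between two groups with the pooled-proportion z-test.
#'
#' @param groupA,groupB `gene_models` data.frames.
#' @return list as returned by [two_proportion_z()], plus group sizes
#'   `nA`, `nB` and the intronless fractions.
#' @export
intronless_fraction_test <- function(groupA, groupB) {
  stop_if_not(nrow(groupA) > 0 && nrow(groupB) > 0, "both groups must be nonempty")
  xa <- sum(groupA$intron_count == 0); xb <- sum(groupB$intron_count == 0)
  res <- two_proportion_z(xa, nrow(groupA), xb, nrow(groupB))
  res$nA <- nrow(groupA); res$nB <- nrow(groupB)
  res
}

#' Kruskal-Wallis + Dunn comparison of intron metrics across groups
#'
#' Intronless genes are excluded before testing (the metric is undefined
#' or trivially zero for them). Groups reduced below two genes by the
#' exclusion are omitted with a warning.
#'
#' @param groups named list of `gene_models` data.frames (>= 2 groups).
#' @param metric `"total_intron_length"` (default) or `"intron_count"`.
#' @return list with `kruskal` (omnibus), `dunn` (pairwise data.frame) and
#'   `group_sizes` (after exclusion).
#' @export
compare_intron_metrics <- function(groups, metric = c("total_intron_length", "intron_count")) {
  metric <- match.arg(metric)
  stop_if_not(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  vals <- lapply(groups, function(g) g[[metric]][g$intron_count > 0])
  small <- vapply(vals, length, 1L) < 2
  if (any(small)) {
    warning("group(s) ", paste(names(groups)[small], collapse = ", "),
            " emptied by intronless exclusion; omitted", call. = FALSE)
    vals <- vals[!small]
  }
  stop_if_not(length(vals) >= 2, "fewer than two groups remain after exclusion")
  list(kruskal = kruskal_wallis(vals),
       dunn = dunn_posthoc(vals),
       group_sizes = vapply(vals, length, 1L))
}

#' Mann-Whitney test of total intron length, top vs bottom half by FC
#'
#' Genes are ranked by their fold-change value (intronless genes excluded
#' first); the total intron lengths of the top and bottom 50% are compared
#' two-sided. With an odd count the median gene is assigned to neither
#' half. The exact null distribution is used for combined n <= 20 without
#' ties, the continuity-corrected normal approximation otherwise.
#'
#' @param models a `gene_models` data.frame.
#' @param fc_value numeric vector, one ranking value per row of `models`
#'   (e.g. the mean signed FC across stresses).
#' @return list with `U`, `p.value`, `exact`, `n_top`, `n_bottom`, and the
#'   two group means; or `NULL` (with a warning) when fewer than 4 genes
#'   remain.
#' @export
intron_length_by_fc_test <- function(models, fc_value) {
  stop_if_not(nrow(models) == length(fc_value), "one fc value per gene required")
  keep <- models$intron_count > 0
  models <- models[keep, , drop = FALSE]
  fc_value <- fc_value[keep]
  if (nrow(models) < 4) {
    warning("fewer than 4 intron-bearing genes; no test", call. = FALSE)
    return(NULL)
  }
  ord <- order(fc_value)
  n <- length(ord)
  half <- n %/% 2
  bottom <- models$total_intron_length[ord[seq_len(half)]]
  top <- models$total_intron_length[ord[(n - half + 1):n]]
  mw <- mann_whitney(top, bottom)
  c(mw, list(n_top = length(top), n_bottom = length(bottom),
             mean_top = mean(top), mean_bottom = mean(bottom)))
}
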