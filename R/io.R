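# Readers and writers for the package's plain-text interchange formats:
# expression TSV + metadata sidecar, FASTA, GFF3, edge-list TSV, Ct CSV.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write an expression dataset to TSV (matrix + metadata sidecar)
#'
#' @param dataset a [stress_expression()].
#' @param matrix_path TSV path for the intensity matrix (`gene_id` column
#'   followed by one column per sample).
#' @param metadata_path TSV path for the sample sidecar (`sample_id`,
#'   `stress`, `timepoint`, `replicate`, `condition`).
#' @return invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, metadata_path) {
  m <- data.frame(gene_id = rownames(dataset$intensities),
                  dataset$intensities, check.names = FALSE)
  write_tsv(m, matrix_path)
  write_tsv(dataset$samples[, c("sample_id", "stress", "timepoint", "replicate",
                                "condition")], metadata_path)
  invisible(c(matrix_path, metadata_path))
}

#' Read an expression dataset from TSV (matrix + metadata sidecar)
#'
#' @param matrix_path,metadata_path paths written by [write_expression()].
#' @return a [stress_expression()].
#' @export
read_expression <- function(matrix_path, metadata_path) {
  m <- read_tsv(matrix_path)
  stop_if_not("gene_id" %in% names(m), "matrix TSV must have a gene_id column")
  mat <- as.matrix(m[, setdiff(names(m), "gene_id"), drop = FALSE])
  rownames(mat) <- m$gene_id
  meta <- read_tsv(metadata_path)
  meta$sample_id <- as.character(meta$sample_id)
  stress_expression(mat[, meta$sample_id, drop = FALSE], meta)
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' Amino-acid FASTA can be read with `type = "AA"`.
#'
#' @param path FASTA path.
#' @param type `"DNA"` (default) or `"AA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' Write a Ct table and its panel metadata
#'
#' @param ct_data list from [simulate_ct_table()].
#' @param ct_path CSV path for `(gene_id, sample_id, ct)` rows.
#' @param samples_path TSV path for the panel metadata.
#' @return invisibly, the two paths.
#' @export
write_ct_table <- function(ct_data, ct_path, samples_path) {
  utils::write.csv(ct_data$ct, ct_path, row.names = FALSE, quote = FALSE)
  write_tsv(ct_data$samples, samples_path)
  invisible(c(ct_path, samples_path))
}

#' Read a Ct table and its panel metadata
#'
#' @param ct_path,samples_path paths written by [write_ct_table()].
#' @param reference_gene id of the internal control gene.
#' @return list with `ct`, `samples`, `reference_gene` (the shape consumed
#'   by [panel_fold_matrix()]).
#' @export
read_ct_table <- function(ct_path, samples_path, reference_gene) {
  ct <- utils::read.csv(ct_path, stringsAsFactors = FALSE)
  samples <- read_tsv(samples_path)
  stop_if_not(all(c("gene_id", "sample_id", "ct") %in% names(ct)),
              "Ct CSV needs gene_id, sample_id, ct columns")
  stop_if_not(reference_gene %in% ct$gene_id, "reference gene absent from Ct table")
  list(ct = ct, samples = samples, reference_gene = reference_gene)
}

#' Transcribed published per-stress DEG count table
#'
#' Loads the package's transcription of the published summary of
#' differentially expressed gene counts in rice roots under eight
#' rhizotoxic stresses (per-stress DEG/up/down and unique counts plus the
#' global class counts), used to exercise the summary-table arithmetic
#' identities.
#'
#' @return data.frame with one row per stressor.
#' @export
published_deg_counts <- function() {
  read_tsv(system.file("extdata", "deg_count_summary.tsv", package = "rhizotox",
                       mustWork = TRUE))
}
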