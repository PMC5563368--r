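IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' IUPAC motif pattern
#'
#' @param iupac consensus string over the IUPAC nucleotide alphabet.
#' @param name optional display name (e.g. `"W-box"`).
#' @return list of class `motif_pattern` with `name`, `iupac`, `length`.
#' @export
motif_pattern <- function(iupac, name = iupac) {
  stop_if_not(is.character(iupac) && length(iupac) == 1L && nzchar(iupac),
              "`iupac` must be a nonempty string")
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_MAP))
  if (length(bad)) {
    stop("invalid IUPAC code '", chars[bad[1]], "' at position ", bad[1], call. = FALSE)
  }
  structure(list(name = name, iupac = iupac, length = nchar(iupac)),
            class = "motif_pattern")
}

#' Built-in stress-response promoter motifs
#'
#' The four cis-elements recurrently enriched in general stress response
#' promoters: the W-box (WRKY binding), an ABRE-like element, the rapid
#' wound/stress response element (RWRE) and the CGCG box (CAMTA binding).
#'
#' @return named list of [motif_pattern()] objects.
#' @export
builtin_motifs <- function() {
  list(`W-box` = motif_pattern("TTGACY", "W-box"),
       `ABRE-like` = motif_pattern("BACGTGKM", "ABRE-like"),
       RWRE = motif_pattern("CGCGTT", "RWRE"),
       `CGCG box` = motif_pattern("SCGCGCS", "CGCG box"))
}

#' Number of concrete sequences matching an IUPAC motif
#'
#' Product of the per-position degeneracies.
#'
#' @param pattern a [motif_pattern()] or IUPAC string.
#' @return integer count.
#' @export
iupac_expand_count <- function(pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  chars <- strsplit(pattern$iupac, "")[[1]]
  prod(nchar(IUPAC_MAP[chars]))
}

as_dna_set <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  if (inherits(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Scan a sequence for motif matches
#'
#' Every window of the pattern length is tested; overlapping matches are
#' reported. Ambiguity codes in the pattern are expanded; `N` in the
#' subject never matches. Reverse-strand matches are located by scanning
#' with the reverse complement of the pattern and are reported by their
#' start on the forward sequence.
#'
#' @param seq a single nucleotide sequence (character or `DNAString`).
#' @param pattern a [motif_pattern()] or IUPAC string.
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame with 1-based `start` and `strand` (`"+"`/`"-"`),
#'   sorted by start. Empty (zero rows) when the sequence is shorter than
#'   the pattern or there is no match.
#' @export
scan_motif <- function(seq, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  subject <- as_dna_set(seq)[[1]]
  if (length(subject) < pattern$length) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  pat <- Biostrings::DNAString(pattern$iupac)
  # fixed = "subject": ambiguities in the pattern act as wildcards while the
  # subject is literal. Subject N would still satisfy a pattern wildcard, so
  # windows overlapping an N are masked out afterwards: N never matches.
  n_pos <- Biostrings::start(Biostrings::matchPattern(Biostrings::DNAString("N"), subject))
  drop_n <- function(starts) {
    if (length(n_pos) == 0 || length(starts) == 0) return(starts)
    keep <- vapply(starts, function(st) {
      !any(n_pos >= st & n_pos <= st + pattern$length - 1L)
    }, TRUE)
    starts[keep]
  }
  fwd <- drop_n(Biostrings::start(Biostrings::matchPattern(pat, subject, fixed = "subject")))
  out <- data.frame(start = fwd, strand = rep("+", length(fwd)))
  if (strands == "both") {
    rc <- Biostrings::reverseComplement(pat)
    rev <- drop_n(Biostrings::start(Biostrings::matchPattern(rc, subject, fixed = "subject")))
    out <- rbind(out, data.frame(start = rev, strand = rep("-", length(rev))))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Logical per-sequence presence of >= 1 motif hit.
motif_presence <- function(seqs, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  set <- as_dna_set(seqs)
  pat <- Biostrings::DNAString(pattern$iupac)
  hit <- Biostrings::vcountPattern(pat, set, fixed = "subject") > 0
  if (strands == "both") {
    rc <- Biostrings::reverseComplement(pat)
    hit <- hit | Biostrings::vcountPattern(rc, set, fixed = "subject") > 0
  }
  # sequences containing N need the window-masked scanner for exactness
  has_n <- Biostrings::vcountPattern(Biostrings::DNAString("N"), set) > 0
  for (i in which(hit & has_n)) {
    hit[i] <- nrow(scan_motif(set[[i]], pattern, strands)) > 0
  }
  hit
}

#' Percentage of genes whose promoter contains a motif
#'
#' Per-gene presence (>= 1 hit), not occurrence counts.
#'
#' @param promoters character vector or `DNAStringSet` of promoter
#'   sequences (one per gene).
#' @inheritParams scan_motif
#' @return percentage in `[0, 100]`.
#' @export
motif_gene_fraction <- function(promoters, pattern, strands = c("both", "forward")) {
  set <- as_dna_set(promoters)
  stop_if_not(length(set) > 0, "empty promoter set")
  100 * mean(motif_presence(set, pattern, strands))
}

#' Permutation test for motif enrichment between two promoter sets
#'
#' The statistic is the difference in per-gene presence fractions
#' (percentage points, group A minus group B). The null is built by
#' shuffling group labels over the pooled genes, preserving group sizes.
#' The one-sided p-value uses the add-one rule
#' `p = (1 + #permuted >= observed) / (1 + n_permutations)`, so `p` is
#' never zero.
#'
#' @param groupA,groupB promoter sets (character vectors or
#'   `DNAStringSet`s); group A is the putatively enriched set.
#' @inheritParams scan_motif
#' @param n_permutations number of label shuffles; default 10000 (values
#'   below 100 trigger a warning).
#' @param seed integer seed for the shuffles (required for
#'   reproducibility).
#' @return list of class `enrichment_result`: `motif`, `fraction_in_groupA`,
#'   `fraction_in_groupB`, `observed_difference`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
motif_permutation_test <- function(groupA, groupB, pattern,
                                   strands = c("both", "forward"),
                                   n_permutations = 10000, seed = 1) {
  strands <- match.arg(strands)
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  a <- as_dna_set(groupA); b <- as_dna_set(groupB)
  stop_if_not(length(a) > 0 && length(b) > 0, "both groups must be nonempty")
  if (n_permutations < 100) warning("n_permutations < 100 gives coarse p-values", call. = FALSE)
  pres_a <- motif_presence(a, pattern, strands)
  pres_b <- motif_presence(b, pattern, strands)
  na <- length(a); nb <- length(b)
  obs <- 100 * (mean(pres_a) - mean(pres_b))
  # canonical order: the null depends only on the presence multiset, and
  # sorting makes the Monte Carlo p invariant to gene order within groups
  pres <- c(sort(pres_a), sort(pres_b))
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(na + nb, na)
      100 * (mean(pres[idx]) - mean(pres[-idx]))
    }, 1.0)
  })
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  structure(list(motif = pattern$name,
                 fraction_in_groupA = 100 * mean(pres_a),
                 fraction_in_groupB = 100 * mean(pres_b),
                 observed_difference = obs, p_value = p,
                 n_permutations = n_permutations, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("motif %s: %.2f%% vs %.2f%% (diff %+.2f pp), p = %.4g [%d permutations]\n",
              x$motif, x$fraction_in_groupA, x$fraction_in_groupB,
              x$observed_difference, x$p_value, x$n_permutations))
  invisible(x)
}
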