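# Nei-Gojobori (NG86) Ka/Ks estimation on pairwise codon alignments, with
# Jukes-Cantor correction for multiple hits.

.rhizotox_cache <- new.env(parent = emptyenv())

split_codons <- function(seq) {
  seq <- toupper(seq)
  stop_if_not(nchar(seq) %% 3 == 0, "sequence length must be divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned amino-acid column to its source codon; gap columns
#' become all-gap codons (`"---"`). Each CDS must translate (standard
#' genetic code) to its ungapped protein; a terminal stop codon is allowed
#' and stripped, internal stops are an error.
#'
#' @param protein_a,protein_b aligned amino-acid sequences (equal length,
#'   gaps as `-`).
#' @param cds_a,cds_b ungapped coding sequences.
#' @return list of class `codon_alignment` with `codons_a`, `codons_b`
#'   (per-column codons incl. `"---"`) and `ungapped_columns`.
#' @export
codon_alignment <- function(protein_a, protein_b, cds_a, cds_b) {
  pa <- strsplit(toupper(protein_a), "")[[1]]
  pb <- strsplit(toupper(protein_b), "")[[1]]
  stop_if_not(length(pa) == length(pb), "aligned proteins must have equal length")
  place <- function(prot_cols, cds, label) {
    codons <- split_codons(cds)
    aa <- translate_codons(codons)
    if (length(aa) > 0 && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (any(aa == "*")) {
      stop("internal stop codon in CDS ", label, " at codon ", which(aa == "*")[1],
           call. = FALSE)
    }
    ungapped <- prot_cols[prot_cols != "-"]
    stop_if_not(length(ungapped) == length(aa),
                paste0("CDS ", label, " length does not match its aligned protein"))
    mism <- which(ungapped != aa)
    if (length(mism)) {
      stop("translation mismatch in ", label, " at residue ", mism[1],
           ": alignment has '", ungapped[mism[1]], "', CDS encodes '", aa[mism[1]], "'",
           call. = FALSE)
    }
    out <- rep("---", length(prot_cols))
    out[prot_cols != "-"] <- codons
    out
  }
  ca <- place(pa, cds_a, "a")
  cb <- place(pb, cds_b, "b")
  structure(list(codons_a = ca, codons_b = cb,
                 ungapped_columns = sum(ca != "---" & cb != "---")),
            class = "codon_alignment")
}

#' NG86 synonymous and nonsynonymous site counts for one codon
#'
#' Each of the nine single-nucleotide mutants of the codon is classified;
#' the synonymous fraction at a position is the proportion of its three
#' mutants that preserve the amino acid (mutants to stop codons count as
#' nonsynonymous). `s` sums the fractions over positions; `n = 3 - s`.
#'
#' @param codon a sense codon (3-mer over ACGT).
#' @return named numeric vector `c(n = ..., s = ...)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  gc <- Biostrings::GENETIC_CODE
  stop_if_not(codon %in% names(gc), "not a codon")
  if (gc[[codon]] == "*") stop("stop codon has no NG86 site counts", call. = FALSE)
  nt <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    syn <- 0L
    for (nb in setdiff(nt, base)) {
      mut <- codon
      substr(mut, pos, pos) <- nb
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) syn <- syn + 1L
    }
    s <- s + syn / 3
  }
  c(n = 3 - s, s = s)
}

ng86_sites_table <- function() {
  if (is.null(.rhizotox_cache$sites)) {
    codons <- sense_codons()
    tab <- t(vapply(codons, ng86_sites, c(n = 0, s = 0)))
    .rhizotox_cache$sites <- tab
  }
  .rhizotox_cache$sites
}

# all permutations of 1..k (k <= 3 in practice)
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in all_perms(k - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

#' Pathway-averaged substitution counts between two codons
#'
#' For codons differing at `k` positions, the `k!` orderings of
#' single-step mutational paths are enumerated; paths passing through a
#' stop codon are excluded and the synonymous/nonsynonymous step counts
#' are averaged over the remaining paths. If every path is blocked by a
#' stop, all paths are included with stop-passing steps counted as
#' nonsynonymous.
#'
#' @param codon1,codon2 sense codons.
#' @return named numeric vector `c(nd = ..., sd = ...)` with
#'   `nd + sd = k`.
#' @export
ng86_codon_diffs <- function(codon1, codon2) {
  gc <- Biostrings::GENETIC_CODE
  c1 <- strsplit(toupper(codon1), "")[[1]]
  c2 <- strsplit(toupper(codon2), "")[[1]]
  diff_pos <- which(c1 != c2)
  k <- length(diff_pos)
  if (k == 0) return(c(nd = 0, sd = 0))
  paths <- all_perms(k)
  score_path <- function(ord, allow_stops) {
    cur <- c1
    nd <- 0; sd <- 0
    for (p in diff_pos[ord]) {
      nxt <- cur
      nxt[p] <- c2[p]
      aa_cur <- gc[[paste0(cur, collapse = "")]]
      aa_nxt <- gc[[paste0(nxt, collapse = "")]]
      if (aa_nxt == "*" && !allow_stops) return(NULL)
      if (aa_cur == aa_nxt && aa_nxt != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  scored <- Filter(Negate(is.null), lapply(paths, score_path, allow_stops = FALSE))
  if (length(scored) == 0) {
    scored <- lapply(paths, score_path, allow_stops = TRUE)
  }
  colMeans(do.call(rbind, scored))
}

#' NG86 site and difference counts for a codon alignment
#'
#' Gap codons are skipped. `N` and `S` are the per-codon site counts
#' averaged between the two sequences and summed over ungapped columns;
#' `Nd` and `Sd` are pathway-averaged difference counts summed over
#' columns.
#'
#' @param alignment a [codon_alignment()].
#' @return named numeric vector `c(N, S, Nd, Sd)`.
#' @export
ng86_pair_counts <- function(alignment) {
  stop_if_not(inherits(alignment, "codon_alignment"), "need a codon_alignment")
  keep <- alignment$codons_a != "---" & alignment$codons_b != "---"
  ca <- alignment$codons_a[keep]
  cb <- alignment$codons_b[keep]
  tab <- ng86_sites_table()
  stop_if_not(all(ca %in% rownames(tab)) && all(cb %in% rownames(tab)),
              "alignment contains stop or ambiguous codons in ungapped columns")
  N <- sum((tab[ca, "n"] + tab[cb, "n"]) / 2)
  S <- sum((tab[ca, "s"] + tab[cb, "s"]) / 2)
  Nd <- 0; Sd <- 0
  differ <- which(ca != cb)
  if (length(differ)) {
    key <- paste(ca[differ], cb[differ])
    for (u in unique(key)) {
      idx <- key == u
      parts <- strsplit(u, " ")[[1]]
      d <- ng86_codon_diffs(parts[1], parts[2])
      Nd <- Nd + d[["nd"]] * sum(idx)
      Sd <- Sd + d[["sd"]] * sum(idx)
    }
  }
  c(N = N, S = S, Nd = Nd, Sd = Sd)
}

#' Ka, Ks and their ratio for a codon alignment (NG86 + Jukes-Cantor)
#'
#' `pN = Nd/N`, `pS = Sd/S`; each proportion is corrected for multiple
#' hits with `K = -(3/4) log(1 - 4p/3)`, undefined when `p >= 3/4`. The
#' ratio is flagged undefined when `Ks = 0` (or when either rate is
#' undefined).
#'
#' @param alignment a [codon_alignment()].
#' @return list of class `kaks_result`: `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `Ka`, `Ks`, `ratio` (NA when undefined) and logical `undefined`.
#' @export
kaks <- function(alignment) {
  cnt <- ng86_pair_counts(alignment)
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  pN <- if (cnt[["N"]] > 0) cnt[["Nd"]] / cnt[["N"]] else NA_real_
  pS <- if (cnt[["S"]] > 0) cnt[["Sd"]] / cnt[["S"]] else NA_real_
  Ka <- jc(pN); Ks <- jc(pS)
  ratio <- if (is.na(Ka) || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(N = cnt[["N"]], S = cnt[["S"]], Nd = cnt[["Nd"]], Sd = cnt[["Sd"]],
                 pN = pN, pS = pS, Ka = Ka, Ks = Ks, ratio = ratio,
                 undefined = is.na(ratio)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: N=%.2f S=%.2f Nd=%.2f Sd=%.2f  Ka=%s Ks=%s  Ka/Ks=%s\n",
              x$N, x$S, x$Nd, x$Sd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              if (is.na(x$ratio)) "undefined" else format(x$ratio, digits = 4)))
  invisible(x)
}

#' Ka/Ks for a set of ortholog pairs
#'
#' Convenience wrapper building codon alignments from matched protein
#' alignments and CDS, then estimating per-pair Ka/Ks.
#'
#' @param protein_a,protein_b,cds_a,cds_b equal-length character vectors
#'   (one entry per pair).
#' @param pair_ids optional ids; default `pair0001...`.
#' @return data.frame with one row per pair: `pair`, `N`, `S`, `Nd`, `Sd`,
#'   `Ka`, `Ks`, `ratio`, `undefined`.
#' @export
kaks_table <- function(protein_a, protein_b, cds_a, cds_b, pair_ids = NULL) {
  n <- length(cds_a)
  stop_if_not(length(cds_b) == n && length(protein_a) == n && length(protein_b) == n,
              "input vectors must have equal length")
  pair_ids <- pair_ids %||% sprintf("pair%04d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    r <- kaks(codon_alignment(protein_a[i], protein_b[i], cds_a[i], cds_b[i]))
    data.frame(pair = pair_ids[i], N = r$N, S = r$S, Nd = r$Nd, Sd = r$Sd,
               Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, undefined = r$undefined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare Ka/Ks distributions of gene categories against a pooled reference
#'
#' Undefined ratios are excluded. Each category is compared to the pooled
#' reference with a two-group Kruskal-Wallis test, Bonferroni-adjusted
#' over categories; an omnibus test across all categories is also
#' reported. Categories with fewer than three defined ratios are flagged
#' and skipped.
#'
#' @param ratios_by_category named list of numeric Ka/Ks vectors.
#' @param reference pooled reference ratios.
#' @return list with `omnibus` and `per_category` (data.frame: `category`,
#'   `n`, `median`, `reference_median`, `p`, `p_adjusted`, `skipped`).
#' @export
kaks_compare_categories <- function(ratios_by_category, reference) {
  clean <- lapply(ratios_by_category, function(x) x[!is.na(x)])
  ref <- reference[!is.na(reference)]
  stop_if_not(length(ref) >= 3, "reference needs >= 3 defined ratios")
  empty <- vapply(clean, length, 1L) == 0
  if (any(empty)) {
    warning("empty categor(ies) omitted: ", paste(names(clean)[empty], collapse = ", "),
            call. = FALSE)
    clean <- clean[!empty]
  }
  usable <- vapply(clean, length, 1L) >= 3
  omnibus <- if (sum(usable) >= 2) kruskal_wallis(clean[usable]) else NULL
  rows <- lapply(names(clean), function(nm) {
    x <- clean[[nm]]
    skip <- length(x) < 3
    p <- if (skip) NA_real_ else kruskal_wallis(list(x, ref))$p.value
    data.frame(category = nm, n = length(x), median = stats::median(x),
               reference_median = stats::median(ref), p = p, skipped = skip,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  per$p_adjusted <- pmin(1, per$p * sum(!per$skipped))
  list(omnibus = omnibus, per_category = per)
}
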