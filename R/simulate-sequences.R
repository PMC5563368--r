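# Synthetic promoter sets, gene models and ortholog pairs with ground truth.

# All concrete expansions of an IUPAC pattern (small motifs only).
iupac_expansions <- function(pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  chars <- strsplit(pattern$iupac, "")[[1]]
  opts <- lapply(chars, function(ch) strsplit(IUPAC_MAP[[ch]], "")[[1]])
  apply(do.call(expand.grid, c(opts, stringsAsFactors = FALSE)), 1, paste0, collapse = "")
}

random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, "")
}

# Rejection-sample `n` sequences with zero motif hits on either strand.
motif_free_dna <- function(n, length, pattern) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(max(8, n - length(out)), length)
    keep <- !motif_presence(cand, pattern, "both")
    out <- c(out, cand[keep])
  }
  out[seq_len(n)]
}

#' Generate promoter sets with exactly controlled motif fractions
#'
#' In each group, exactly `round(fraction * n)` promoters receive one
#' planted exact instance of the motif (a random concrete expansion at a
#' random position inside an otherwise motif-free backbone); the remaining
#' promoters are rejection-sampled to contain zero instances on either
#' strand, so scanner-measured per-gene fractions equal the planted
#' fractions exactly.
#'
#' @param n_gsr,n_background group sizes.
#' @param pattern a [motif_pattern()] or IUPAC string.
#' @param planted_fraction_gsr,planted_fraction_bg fractions in `[0, 1]`.
#' @param length promoter length in bp (must be >= the motif length).
#' @param seed integer seed.
#' @return list with `gsr` and `background` (named character vectors of
#'   sequences) and `truth` (data.frame: `set`, `seq_id`, `planted`).
#' @export
simulate_promoters <- function(n_gsr, n_background, pattern,
                               planted_fraction_gsr, planted_fraction_bg,
                               length = 1000, seed = 1) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  stop_if_not(planted_fraction_gsr >= 0 && planted_fraction_gsr <= 1 &&
                planted_fraction_bg >= 0 && planted_fraction_bg <= 1,
              "fractions must lie in [0, 1]")
  if (length < pattern$length) {
    stop("promoter length (", length, ") shorter than motif (", pattern$length, ")",
         call. = FALSE)
  }
  with_seed(substream_seed(seed, "promoters"), {
    expans <- iupac_expansions(pattern)
    make_group <- function(n, frac, prefix) {
      n_plant <- round(frac * n)
      seqs <- motif_free_dna(n, length, pattern)
      if (n_plant > 0) {
        for (i in seq_len(n_plant)) {
          inst <- sample(expans, 1)
          pos <- sample.int(length - pattern$length + 1L, 1)
          substr(seqs[i], pos, pos + pattern$length - 1L) <- inst
        }
      }
      names(seqs) <- sprintf("%s%04d", prefix, seq_len(n))
      list(seqs = seqs, planted = seq_len(n) <= n_plant)
    }
    a <- make_group(n_gsr, planted_fraction_gsr, "gsr")
    b <- make_group(n_background, planted_fraction_bg, "bg")
    truth <- data.frame(set = rep(c("gsr", "background"), c(n_gsr, n_background)),
                        seq_id = c(names(a$seqs), names(b$seqs)),
                        planted = c(a$planted, b$planted),
                        stringsAsFactors = FALSE)
    list(gsr = a$seqs, background = b$seqs, truth = truth)
  })
}

#' Generate gene models (GFF3) with controlled intron architecture
#'
#' Each group is defined by sampling functions for the intron count and
#' for individual intron lengths. Genes are laid out head-to-tail on a
#' single synthetic chromosome with one mRNA and explicit exon features;
#' the emitted text round-trips through [read_gene_models()].
#'
#' @param groups named list; each element is a list with `n` (genes),
#'   `intron_count` (function(n) -> integer vector >= 0) and
#'   `intron_length` (function(k) -> k lengths >= 1).
#' @param exon_length function(k) -> k exon lengths; default uniform
#'   100-300 bp.
#' @param seed integer seed.
#' @return list with `gff3` (character vector of GFF3 lines) and `truth`
#'   (data.frame: `gene`, `group`, `intron_count`, `total_intron_length`).
#' @export
simulate_gene_models <- function(groups,
                                 exon_length = function(k) sample(100:300, k, replace = TRUE),
                                 seed = 1) {
  stop_if_not(is.list(groups) && length(groups) >= 1 && !is.null(names(groups)),
              "`groups` must be a named list")
  with_seed(substream_seed(seed, "gene_models"), {
    lines <- c("##gff-version 3")
    truth <- list()
    pos <- 1L
    gi <- 0L
    for (gname in names(groups)) {
      gr <- groups[[gname]]
      counts <- gr$intron_count(gr$n)
      stop_if_not(all(counts >= 0), "intron counts must be >= 0")
      for (i in seq_len(gr$n)) {
        gi <- gi + 1L
        gid <- sprintf("gene%05d", gi)
        k <- counts[i]
        ex_len <- exon_length(k + 1L)
        in_len <- if (k > 0) gr$intron_length(k) else integer(0)
        stop_if_not(all(in_len >= 1), "intron lengths must be >= 1")
        starts <- ends <- integer(k + 1L)
        at <- pos
        for (e in seq_len(k + 1L)) {
          starts[e] <- at
          ends[e] <- at + ex_len[e] - 1L
          at <- ends[e] + (if (e <= k) in_len[e] else 0L) + 1L
        }
        g_start <- starts[1]; g_end <- ends[k + 1L]
        mid <- paste0(gid, ".1")
        lines <- c(lines,
                   sprintf("chr1\trhizotox\tgene\t%d\t%d\t.\t+\t.\tID=%s", g_start, g_end, gid),
                   sprintf("chr1\trhizotox\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                           g_start, g_end, mid, gid),
                   sprintf("chr1\trhizotox\texon\t%d\t%d\t.\t+\t.\tID=%s.exon%d;Parent=%s",
                           starts, ends, mid, seq_len(k + 1L), mid))
        truth[[gi]] <- data.frame(gene = gid, group = gname, intron_count = k,
                                  total_intron_length = sum(in_len),
                                  stringsAsFactors = FALSE)
        pos <- g_end + 500L  # intergenic spacer
      }
    }
    list(gff3 = lines, truth = do.call(rbind, truth))
  })
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Simulate diverged ortholog CDS pairs under a given omega
#'
#' Each pair starts from a random stop-free codon sequence; one copy then
#' accumulates point mutations: a Poisson(`codons_per_gene *
#' branch_mutations`) number of proposals, each a uniform single-nucleotide
#' change at a uniform position. Proposals creating stop codons are
#' rejected; synonymous proposals are always accepted; nonsynonymous
#' proposals are accepted with probability `min(1, omega)`. The neutral
#' limit (`omega = 1`) therefore has dN/dS = 1 by construction.
#'
#' @param n_pairs number of ortholog pairs.
#' @param codons_per_gene codons per sequence.
#' @param omega relative acceptance probability of nonsynonymous changes
#'   (>= 0).
#' @param branch_mutations expected proposed substitutions per codon along
#'   the branch.
#' @param seed integer seed.
#' @return list with `cds_a`, `cds_b` (named character vectors),
#'   `protein_a`, `protein_b` (aligned amino-acid sequences; no gaps are
#'   introduced by this generator) and `truth` (data.frame: `pair`,
#'   `omega`, `n_proposed`, `n_accepted`, `n_nonsyn`).
#' @export
simulate_ortholog_pairs <- function(n_pairs, codons_per_gene, omega,
                                    branch_mutations = 0.4, seed = 1) {
  stop_if_not(omega >= 0, "omega must be >= 0")
  stop_if_not(branch_mutations >= 0, "branch_mutations must be >= 0")
  with_seed(substream_seed(seed, "orthologs"), {
    sense <- sense_codons()
    nt <- c("A", "C", "G", "T")
    gc <- Biostrings::GENETIC_CODE
    cds_a <- cds_b <- prot_a <- prot_b <- character(n_pairs)
    truth <- data.frame(pair = sprintf("pair%04d", seq_len(n_pairs)),
                        omega = omega, n_proposed = 0L, n_accepted = 0L,
                        n_nonsyn = 0L, stringsAsFactors = FALSE)
    for (i in seq_len(n_pairs)) {
      anc <- sample(sense, codons_per_gene, replace = TRUE)
      der <- anc
      m <- stats::rpois(1, codons_per_gene * branch_mutations)
      acc <- 0L; nonsyn <- 0L
      for (ev in seq_len(m)) {
        ci <- sample.int(codons_per_gene, 1)
        pos <- sample.int(3L, 1)
        old <- der[ci]
        base <- substr(old, pos, pos)
        new_base <- sample(setdiff(nt, base), 1)
        cand <- old
        substr(cand, pos, pos) <- new_base
        if (gc[[cand]] == "*") next
        if (gc[[cand]] == gc[[old]]) {
          der[ci] <- cand; acc <- acc + 1L
        } else if (stats::runif(1) < min(1, omega)) {
          der[ci] <- cand; acc <- acc + 1L; nonsyn <- nonsyn + 1L
        }
      }
      cds_a[i] <- paste0(anc, collapse = "")
      cds_b[i] <- paste0(der, collapse = "")
      prot_a[i] <- paste0(translate_codons(anc), collapse = "")
      prot_b[i] <- paste0(translate_codons(der), collapse = "")
      truth$n_proposed[i] <- m
      truth$n_accepted[i] <- acc
      truth$n_nonsyn[i] <- nonsyn
    }
    ids <- truth$pair
    names(cds_a) <- paste0(ids, "_a"); names(cds_b) <- paste0(ids, "_b")
    names(prot_a) <- paste0(ids, "_a"); names(prot_b) <- paste0(ids, "_b")
    list(cds_a = cds_a, cds_b = cds_b, protein_a = prot_a, protein_b = prot_b,
         truth = truth)
  })
}
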