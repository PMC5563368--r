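# Shared fixtures and independent oracles used across test files.

# i.i.d. uniform random DNA sequences (the common-distribution null for
# calibration studies).
rand_seqs <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# Build a tiny stress_expression by hand: one stress, one timepoint,
# `reps` control + treated columns per gene from the rows of `ctrl` and
# `trt` matrices.
tiny_dataset <- function(ctrl, trt, stress = "Cu", timepoint = "1h") {
  stopifnot(nrow(ctrl) == nrow(trt))
  reps <- ncol(ctrl)
  mat <- cbind(ctrl, trt)
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  ids <- c(paste0("c", seq_len(reps)), paste0("t", seq_len(reps)))
  colnames(mat) <- ids
  meta <- data.frame(sample_id = ids, stress = stress, timepoint = timepoint,
                     replicate = rep(seq_len(reps), 2),
                     condition = rep(c("control", "treated"), each = reps))
  stress_expression(mat, meta)
}

# Naive window-by-window IUPAC scanner: the oracle for scan_motif.
naive_scan <- function(seq, iupac, strands = "both") {
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  match_at <- function(s, pat, pos) {
    for (j in seq_along(pat)) {
      ch <- substr(s, pos + j - 1, pos + j - 1)
      if (!(ch %in% codes[[pat[j]]])) return(FALSE)  # N in subject never matches
    }
    TRUE
  }
  revcomp <- function(p) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
              W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N")
    rev(unname(comp[p]))
  }
  pat <- strsplit(iupac, "")[[1]]
  L <- nchar(seq)
  hits <- data.frame(start = integer(0), strand = character(0))
  if (L >= length(pat)) {
    for (pos in seq_len(L - length(pat) + 1)) {
      if (match_at(seq, pat, pos)) {
        hits <- rbind(hits, data.frame(start = pos, strand = "+"))
      }
      if (strands == "both" && match_at(seq, revcomp(pat), pos)) {
        hits <- rbind(hits, data.frame(start = pos, strand = "-"))
      }
    }
  }
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Quadratic-time brute force of the BH step-up definition:
# q_i = min over j with p_(j) >= p_i of p_(j) * n / rank(p_(j)), capped at 1.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    cand <- ps[i:n] * n / (i:n)
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# Independent NG86 site-count oracle built on seqinr's translation.
oracle_sites <- function(codon) {
  tr <- function(cdn) seqinr::translate(strsplit(cdn, "")[[1]])
  nt <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(nt, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nb
      if (tr(mut) != "*" && tr(mut) == tr(codon)) s <- s + 1 / 3
    }
  }
  c(n = 3 - s, s = s)
}

# Explicit factorial-enumeration oracle for pathway-averaged differences.
oracle_diffs <- function(c1, c2) {
  tr <- function(cdn) seqinr::translate(strsplit(cdn, "")[[1]])
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  dp <- which(a != b)
  k <- length(dp)
  if (k == 0) return(c(nd = 0, sd = 0))
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  score <- function(ord, allow) {
    cur <- a; nd <- 0; sd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- tr(paste0(cur, collapse = "")); aa2 <- tr(paste0(nxt, collapse = ""))
      if (aa2 == "*" && !allow) return(NULL)
      if (aa1 == aa2 && aa2 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd = nd, sd = sd)
  }
  paths <- perm_list(dp)
  res <- Filter(Negate(is.null), lapply(paths, score, allow = FALSE))
  if (length(res) == 0) res <- lapply(paths, score, allow = TRUE)
  colMeans(do.call(rbind, res))
}

# The synthetic configuration used by the recovery studies.
recovery_config <- function(seed, noise_sd) {
  synthetic_config(n_genes = 2000,
                   planted_counts = list(gsr_up = 100, generally_down = 20,
                                         unique_up = 10, unique_down = 0,
                                         background = 100, low_regulated = 50),
                   noise_sd = noise_sd, seed = seed)
}
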