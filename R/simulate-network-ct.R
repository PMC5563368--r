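# Synthetic interaction networks and qPCR Ct tables with ground truth.

#' Generate a network with planted hubs
#'
#' Background connectivity is Erdos-Renyi with edge probability
#' `background_degree_mean / (n_nodes - 1)`; each planted hub is
#' additionally wired to `hub_degree` distinct random partners. The result
#' is a simple undirected graph (no self-loops, no duplicate edges).
#'
#' @param n_nodes node count.
#' @param planted_hubs number of hub nodes.
#' @param hub_degree edges added per hub (must exceed
#'   `background_degree_mean`).
#' @param background_degree_mean expected background degree.
#' @param regulator_labels optional character vector of node ids to label
#'   with role `"TF"` (all other nodes get `"other"`).
#' @param seed integer seed.
#' @return list with `edges` (data.frame `node_a`, `node_b`), `roles`
#'   (data.frame `node`, `role`) and `truth` (data.frame `node`,
#'   `is_hub`).
#' @export
simulate_network <- function(n_nodes, planted_hubs, hub_degree,
                             background_degree_mean = 3,
                             regulator_labels = NULL, seed = 1) {
  stop_if_not(hub_degree > background_degree_mean,
              "hub_degree must exceed background_degree_mean")
  stop_if_not(planted_hubs >= 0 && planted_hubs < n_nodes, "invalid planted_hubs")
  with_seed(substream_seed(seed, "network"), {
    nodes <- sprintf("n%04d", seq_len(n_nodes))
    hubs <- nodes[seq_len(planted_hubs)]
    p_bg <- min(1, background_degree_mean / (n_nodes - 1))
    # background edges over all unordered pairs
    pairs <- utils::combn(n_nodes, 2)
    keep <- stats::runif(ncol(pairs)) < p_bg
    edges <- cbind(nodes[pairs[1, keep]], nodes[pairs[2, keep]])
    for (h in hubs) {
      partners <- sample(setdiff(nodes, h), hub_degree)
      edges <- rbind(edges, cbind(h, partners))
    }
    # canonical order + dedup
    a <- pmin(edges[, 1], edges[, 2]); b <- pmax(edges[, 1], edges[, 2])
    keep <- !duplicated(paste(a, b)) & a != b
    edges <- data.frame(node_a = a[keep], node_b = b[keep], stringsAsFactors = FALSE)
    roles <- data.frame(node = nodes,
                        role = ifelse(nodes %in% (regulator_labels %||% character(0)),
                                      "TF", "other"),
                        stringsAsFactors = FALSE)
    list(edges = edges,
         roles = roles,
         truth = data.frame(node = nodes, is_hub = nodes %in% hubs,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a qPCR Ct table with planted fold inductions
#'
#' Ct values are constructed so that delta-delta-Ct quantification recovers
#' the planted fold inductions exactly (one cycle fewer per 2-fold
#' induction, reference gene constant). One control sample plus one treated
#' sample per panel; technical replicates are emitted as repeated rows per
#' sample.
#'
#' @param stressor_panels named list: panel label -> character vector of
#'   stressors applied in that panel.
#' @param biomarker_profile named list: gene id -> named numeric vector of
#'   fold inductions per panel (names must cover all panels; folds > 0).
#' @param reference_gene id of the internal control gene; default
#'   `"tubulin_a"`.
#' @param reference_ct,control_ct baseline Ct of the reference gene and of
#'   targets in control samples.
#' @param replicates technical replicates per reaction; default 3.
#' @param ct_sd technical noise on Ct cycles; default 0 (exact recovery).
#' @param seed integer seed.
#' @return list with `ct` (data.frame `gene_id`, `sample_id`, `ct`),
#'   `samples` (data.frame `sample_id`, `panel`, `stresses`, `condition`)
#'   and `truth` (data.frame `gene`, `panel`, `fold`).
#' @export
simulate_ct_table <- function(stressor_panels, biomarker_profile,
                              reference_gene = "tubulin_a",
                              reference_ct = 20, control_ct = 28,
                              replicates = 3, ct_sd = 0, seed = 1) {
  stop_if_not(is.list(stressor_panels) && !is.null(names(stressor_panels)),
              "`stressor_panels` must be a named list")
  stop_if_not(all(unlist(lapply(biomarker_profile, function(f) all(f > 0)))),
              "fold inductions must be > 0")
  panels <- names(stressor_panels)
  for (g in names(biomarker_profile)) {
    stop_if_not(all(panels %in% names(biomarker_profile[[g]])),
                paste0("gene '", g, "' lacks a fold for some panel"))
  }
  with_seed(substream_seed(seed, "ct_table"), {
    samples <- data.frame(
      sample_id = c(paste0(panels, "_treated"), "water_control"),
      panel = c(panels, "control"),
      stresses = c(vapply(stressor_panels, paste, "", collapse = "+"), ""),
      condition = c(rep("treated", length(panels)), "control"),
      stringsAsFactors = FALSE)
    rows <- list()
    emit <- function(gene, sample, ct) {
      noise <- if (ct_sd > 0) stats::rnorm(replicates, 0, ct_sd) else 0
      rows[[length(rows) + 1L]] <<- data.frame(gene_id = gene, sample_id = sample,
                                               ct = ct + noise, stringsAsFactors = FALSE)
    }
    for (s in samples$sample_id) emit(reference_gene, s, reference_ct)
    truth <- list()
    for (g in names(biomarker_profile)) {
      emit(g, "water_control", control_ct)
      for (pn in panels) {
        fold <- biomarker_profile[[g]][[pn]]
        emit(g, paste0(pn, "_treated"), control_ct - log2(fold))
        truth[[length(truth) + 1L]] <- data.frame(gene = g, panel = pn, fold = fold,
                                                  stringsAsFactors = FALSE)
      }
    }
    list(ct = do.call(rbind, rows), samples = samples,
         truth = do.call(rbind, truth), reference_gene = reference_gene)
  })
}

#' The five leave-one-out combined-stress panels
#'
#' The default combined-stress design: five panels over the five
#' metal/metalloid stressors (As(V), Cd, Hg, Cu, Cr), each omitting exactly
#' one, so every stressor is absent from exactly one panel.
#'
#' @param metals the stressor set; default `c("AsV", "Cd", "Hg", "Cu",
#'   "Cr")`.
#' @return named list of stressor subsets.
#' @export
leave_one_out_panels <- function(metals = c("AsV", "Cd", "Hg", "Cu", "Cr")) {
  panels <- lapply(seq_along(metals), function(i) metals[-i])
  names(panels) <- paste0("minus_", metals)
  panels
}
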