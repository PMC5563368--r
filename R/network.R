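#' Load a gene interaction network from an edge-list TSV
#'
#' Two-column TSV (`node_a`, `node_b`, header optional). Self-loops are
#' dropped (count logged via message) and duplicate undirected edges are
#' collapsed, yielding a simple undirected graph.
#'
#' @param path TSV file path, or a data.frame with two columns.
#' @param roles optional data.frame (`node`, `role`) or path to a role
#'   TSV; roles are attached as the vertex attribute `role`.
#' @return an [igraph::graph] object.
#' @export
read_edge_list <- function(path, roles = NULL) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    df <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                        col.names = c("node_a", "node_b"), comment.char = "#"),
      error = function(e) stop("malformed edge list '", path, "': ", conditionMessage(e),
                               call. = FALSE))
    if (nrow(df) > 0 && identical(tolower(unlist(df[1, ])), c("node_a", "node_b"))) {
      df <- df[-1, , drop = FALSE]
    }
  }
  if (nrow(df) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  stop_if_not(ncol(df) >= 2, "edge list needs two columns")
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  bad <- is.na(a) | is.na(b) | a == "" | b == ""
  if (any(bad)) {
    stop("malformed edge list line ", which(bad)[1], call. = FALSE)
  }
  loops <- a == b
  if (any(loops)) message("read_edge_list: dropped ", sum(loops), " self-loop(s)")
  a2 <- pmin(a[!loops], b[!loops]); b2 <- pmax(a[!loops], b[!loops])
  keep <- !duplicated(paste(a2, b2))
  g <- igraph::graph_from_data_frame(data.frame(a2[keep], b2[keep]), directed = FALSE)
  if (!is.null(roles)) {
    if (!is.data.frame(roles)) {
      roles <- utils::read.table(roles, sep = "\t", header = TRUE,
                                 colClasses = "character")
    }
    idx <- match(igraph::V(g)$name, roles$node)
    igraph::V(g)$role <- ifelse(is.na(idx), "other", roles$role[idx])
  }
  g
}

#' Top hub nodes by degree
#'
#' Nodes ranked by degree descending, ties broken lexicographically by
#' node id; exactly `min(k, |V|)` entries are returned.
#'
#' @param network an igraph graph.
#' @param k number of hubs requested (>= 1).
#' @return data.frame with columns `node`, `degree`, in rank order.
#' @export
top_hubs <- function(network, k) {
  stop_if_not(k >= 1, "k must be >= 1")
  deg <- igraph::degree(network)
  nm <- igraph::V(network)$name %||% as.character(seq_len(igraph::vcount(network)))
  ord <- order(-deg, nm)
  n <- min(k, length(deg))
  data.frame(node = nm[ord][seq_len(n)], degree = unname(deg[ord])[seq_len(n)],
             stringsAsFactors = FALSE)
}

#' Terminal regulators: connected regulators with no regulator neighbours
#'
#' Returns the members of `regulator_set` that have at least one edge and
#' whose neighbourhood contains no other member of `regulator_set` — the
#' regulators wired directly (and only) to non-regulatory genes.
#'
#' @param network an igraph graph.
#' @param regulator_set character vector of regulator node ids (must be a
#'   subset of the node set).
#' @return data.frame with `node` and list-column `neighbors`.
#' @export
terminal_regulators <- function(network, regulator_set) {
  nm <- igraph::V(network)$name
  missing <- setdiff(regulator_set, nm)
  stop_if_not(length(missing) == 0,
              paste("regulator(s) not in network:", paste(utils::head(missing, 5), collapse = ", ")))
  out <- list()
  for (r in regulator_set) {
    nb <- igraph::V(network)$name[igraph::neighbors(network, r)]
    if (length(nb) >= 1 && !any(nb %in% regulator_set)) {
      row <- data.frame(node = r, stringsAsFactors = FALSE)
      row$neighbors <- list(sort(nb))
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0) {
    res <- data.frame(node = character(0))
    res$neighbors <- list()
    return(res)
  }
  do.call(rbind, out)
}
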