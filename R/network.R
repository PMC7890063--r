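#' Build a sequence similarity network
#'
#' Nodes are enzymes; an undirected edge joins two enzymes iff their
#' alignment score is at or above the threshold (the EFI-EST style
#' "alignment score" cutoff; here a raw pairwise score, see the methods
#' vignette for the calibration note). Isolated nodes are retained so that
#' singletons remain visible in Cytoscape.
#'
#' @param score_matrix Symmetric numeric matrix with enzyme ids as dimnames.
#' @param threshold Minimum score for an edge (default 16).
#' @return An object of class `ssn`: list with `graph` (igraph), `threshold`
#'   and `nodes`.
#' @export
build_ssn <- function(score_matrix, threshold = 16) {
  m <- as.matrix(score_matrix)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-8))
    stop("score matrix must be square and symmetric")
  ids <- rownames(m) %||% paste0("node", seq_len(nrow(m)))
  adj <- (m >= threshold)
  diag(adj) <- FALSE
  dimnames(adj) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g)
  if (nrow(el))
    igraph::E(g)$score <- m[cbind(el[, 1], el[, 2])]
  structure(list(graph = g, threshold = threshold, nodes = ids),
            class = "ssn")
}

#' @export
print.ssn <- function(x, ...) {
  cat(sprintf("SSN: %d node(s), %d edge(s) at threshold %g, %d cluster(s)\n",
              length(x$nodes), igraph::ecount(x$graph), x$threshold,
              igraph::count_components(x$graph)))
  invisible(x)
}

#' Connected-component membership of an SSN
#'
#' @param net An `ssn`.
#' @return Named integer vector mapping node id to cluster index.
#' @export
ssn_clusters <- function(net) {
  stopifnot(inherits(net, "ssn"))
  igraph::components(net$graph)$membership
}

#' Write an SSN as GraphML and/or edge-list TSV
#'
#' Both formats load directly into Cytoscape. Optional per-node attributes
#' (label, kingdom, profile, ...) are attached to the GraphML nodes and can
#' also be written as a node-attribute TSV.
#'
#' @param net An `ssn`.
#' @param graphml,edges,node_attributes_path Output paths (any may be NULL).
#' @param attributes Optional data frame of node attributes with an `id`
#'   column matching the node ids.
#' @export
write_ssn <- function(net, graphml = NULL, edges = NULL,
                      attributes = NULL, node_attributes_path = NULL) {
  stopifnot(inherits(net, "ssn"))
  g <- net$graph
  if (!is.null(attributes)) {
    stopifnot("id" %in% names(attributes))
    idx <- match(igraph::V(g)$name, attributes$id)
    for (col in setdiff(names(attributes), "id"))
      g <- igraph::set_vertex_attr(g, col, value = attributes[[col]][idx])
  }
  if (!is.null(graphml))
    igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edges)) {
    el <- igraph::as_edgelist(g)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     score = if (nrow(el)) igraph::E(g)$score else numeric(0))
    utils::write.table(df, edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(node_attributes_path) && !is.null(attributes))
    utils::write.table(attributes, node_attributes_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(net)
}
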