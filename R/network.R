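#' Build an F_ST-threshold connectivity network
#'
#' Sites are nodes; an undirected edge joins two sites whenever their
#' pairwise F_ST is at or below the threshold (genetically similar sites
#' are connected, strongly differentiated pairs are not).  Isolated nodes
#' are retained, so a site differentiated from everything (minimum
#' pairwise F_ST above the threshold) appears with degree zero.
#'
#' @param fst_matrix a symmetric labelled F_ST matrix (or anything
#'   [as_labelled_matrix()] accepts).
#' @param threshold inclusion cutoff; edges with F_ST above it are
#'   removed.  0.04 is the conventional choice here: the lowest value
#'   connecting all but the fully isolated site.
#' @return an `igraph` graph with vertex attribute `name` and edge
#'   attribute `weight` (the pairwise F_ST).
#' @examples
#' g <- build_network(port_phillip_fst(), threshold = 0.04)
#' igraph::degree(g)["Point Lonsdale"]  # 0: isolated site
#' @export
build_network <- function(fst_matrix, threshold = 0.04) {
  m <- as_labelled_matrix(fst_matrix)
  check_symmetric(m, "fst_matrix")
  if (threshold <= 0) stop("threshold must be > 0.", call. = FALSE)
  adj <- (m <= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  edges <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- m[edges]
  g
}

#' Node degree and betweenness centrality of a site network
#'
#' Degree counts a node's direct connections.  Betweenness centrality
#' counts the shortest paths passing through a node (endpoints excluded),
#' splitting ties fractionally; in weighted mode (the default) the
#' pairwise F_ST is the edge length, so paths prefer genetically similar
#' stepping stones.  Scores are unnormalized.
#'
#' @param graph an `igraph` graph from [build_network()], or an F_ST
#'   matrix (then `threshold` is applied first).
#' @param weighted use F_ST edge lengths for betweenness (default `TRUE`).
#' @param threshold passed to [build_network()] when `graph` is a matrix.
#' @return a tibble `site`, `degree`, `betweenness`.
#' @export
network_metrics <- function(graph, weighted = TRUE, threshold = 0.04) {
  if (!inherits(graph, "igraph")) graph <- build_network(graph, threshold)
  w <- NULL
  if (weighted && igraph::ecount(graph) > 0) {
    # Dijkstra needs positive lengths; F_ST can be 0 (or negative when
    # unconstrained estimates are kept), so floor edge lengths at ~0
    w <- pmax(igraph::E(graph)$weight, 1e-9)
  }
  tibble::tibble(
    site = igraph::V(graph)$name,
    degree = as.integer(igraph::degree(graph)),
    betweenness = unname(igraph::betweenness(graph, weights = w,
                                             normalized = FALSE))
  )
}

#' Edge list of a site network
#'
#' @param graph an `igraph` graph from [build_network()].
#' @return a tibble `from`, `to`, `weight` (pairwise F_ST).
#' @export
network_edges <- function(graph) {
  el <- igraph::as_edgelist(graph)
  tibble::tibble(from = el[, 1], to = el[, 2],
                 weight = igraph::E(graph)$weight %||% rep(NA_real_, nrow(el)))
}
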