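#' Plot a beta-regression fit
#'
#' Observed genotypic richness against fitted means with the 1:1 line; a
#' well-specified fit scatters tightly around the diagonal.
#'
#' @param object a `beta_reg` fit.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.beta_reg <- function(object, ...) {
  df <- tibble::tibble(fitted = object$fitted, observed = object$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "fitted mean", y = "observed",
                  title = sprintf("Beta regression (pseudo-R² = %.2f)",
                                  object$pseudo_r2)) +
    ggplot2::theme_minimal()
}

#' Plot a dispersal result as a source-by-destination heat map
#'
#' @param object a `dispersal_result`.
#' @param what `"probability"` or `"flow"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dispersal_result <- function(object,
                                      what = c("probability", "flow"), ...) {
  what <- match.arg(what)
  m <- object[[what]]
  df <- matrix_to_tibble(m, diagonal = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$to, .data$from,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = "destination", y = "source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an F_ST-threshold site network
#'
#' Nodes are sites (sized by degree), edges join pairs whose F_ST is at
#' or below the threshold; isolated sites remain visible.
#'
#' @param graph an `igraph` graph from [build_network()] or an F_ST
#'   matrix.
#' @param threshold passed to [build_network()] when `graph` is a matrix.
#' @param seed layout seed for reproducible node placement.
#' @return a ggplot.
#' @export
plot_site_network <- function(graph, threshold = 0.04, seed = 42) {
  if (!inherits(graph, "igraph")) graph <- build_network(graph, threshold)
  set.seed(seed)
  xy <- igraph::layout_with_fr(graph)
  nodes <- tibble::tibble(site = igraph::V(graph)$name,
                          x = xy[, 1], y = xy[, 2],
                          degree = as.integer(igraph::degree(graph)))
  el <- igraph::as_edgelist(graph)
  edges <- tibble::tibble(
    x = nodes$x[match(el[, 1], nodes$site)],
    y = nodes$y[match(el[, 1], nodes$site)],
    xend = nodes$x[match(el[, 2], nodes$site)],
    yend = nodes$y[match(el[, 2], nodes$site)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60") +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(.data$x, .data$y, size = .data$degree),
      colour = "darkgreen") +
    ggplot2::geom_text(data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$site),
      vjust = -1, size = 3) +
    ggplot2::scale_size_continuous(range = c(2, 8)) +
    ggplot2::theme_void() +
    ggplot2::labs(size = "degree")
}
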