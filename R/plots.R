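#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Portrait heatmap
#'
#' Renders a portrait as a tile map with the diverging
#' blue-green-red scale conventional for such maps: green at 0
#' (unchanged), red for up- and blue for down-regulated units.
#'
#' @param object A `psf_portrait`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psf_portrait <- function(object, ...) {
  lim <- max(abs(object$value), na.rm = TRUE)
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$col, y = .data$row,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "#1B7837",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  name = "log2 activity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(object, "owner"), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Spot map overview
#'
#' Shows the detected spots on the grid, colored by polarity and
#' annotated with their labels at the spot centroids.
#'
#' @param object A `spot_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spot_map <- function(object, ...) {
  spots <- object$spots
  centers <- spots |>
    dplyr::group_by(.data$label, .data$polarity) |>
    dplyr::summarise(row = mean(.data$row), col = mean(.data$col),
                     .groups = "drop")
  ggplot2::ggplot(spots, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$polarity)) +
    ggplot2::geom_text(data = centers, ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_manual(
      values = c(up = "#B2182B", down = "#2166AC")) +
    ggplot2::scale_y_reverse(limits = c(object$rows + 0.5, 0.5)) +
    ggplot2::scale_x_continuous(limits = c(0.5, object$cols + 0.5)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the disease similarity graph
#'
#' Thin wrapper over igraph's plotting with edge widths proportional to
#' multiplicity and vertices colored by walktrap community.
#'
#' @param x A `disease_graph`.
#' @param communities Optional [detect_communities()] tibble for vertex
#'   coloring.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.disease_graph <- function(x, communities = NULL, ...) {
  g <- x$graph
  col <- "grey80"
  if (!is.null(communities)) {
    mem <- communities$community[match(igraph::V(g)$name,
                                       communities$disease)]
    col <- grDevices::hcl.colors(max(mem), "Dark 3")[mem]
  }
  w <- igraph::E(g)$weight
  igraph::plot.igraph(g, vertex.color = col,
                      edge.width = if (length(w)) w else 1, ...)
  invisible(x)
}
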