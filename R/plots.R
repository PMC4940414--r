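#' Plot a trait network
#'
#' Force-directed layout of the network: edge colour encodes the sign of the
#' correlation, edge width its absolute value, node size the degree, node
#' shape the molecular class. A deterministic layout seed keeps plots
#' reproducible.
#'
#' @param object A `trait_network`.
#' @param layout_seed Seed for the Fruchterman-Reingold layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_network
#' @export
autoplot.trait_network <- function(object, layout_seed = 1L, ...) {
  xy <- with_seed(layout_seed, igraph::layout_with_fr(object))
  nodes <- tibble(
    feature_id = igraph::V(object)$name,
    x = xy[, 1], y = xy[, 2],
    degree = as.numeric(igraph::degree(object)),
    molecular_class = igraph::vertex_attr(object, "molecular_class") %||%
      rep("feature", igraph::vcount(object))
  )
  el <- igraph::as_edgelist(object)
  edges <- tibble(
    xa = nodes$x[match(el[, 1], nodes$feature_id)],
    ya = nodes$y[match(el[, 1], nodes$feature_id)],
    xb = nodes$x[match(el[, 2], nodes$feature_id)],
    yb = nodes$y[match(el[, 2], nodes$feature_id)],
    sign = factor(ifelse(igraph::E(object)$sign >= 0, "positive", "negative"),
                  levels = c("positive", "negative")),
    abs_rho = abs(igraph::E(object)$rho)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, colour = .data$sign,
                   linewidth = .data$abs_rho),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree,
                   shape = .data$molecular_class)
    ) +
    ggplot2::scale_colour_manual(
      values = c(positive = "#2166ac", negative = "#b2182b")
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "correlation", size = "degree", shape = NULL)
}

#' Plot the heritability histogram
#'
#' Bar plot of the relative frequency of heritability estimates per 0.1-wide
#' bin, optionally split by molecular class (as produced by
#' [h2_histogram()]).
#'
#' @param bins Output of [h2_histogram()].
#' @return A ggplot object.
#' @export
plot_h2_histogram <- function(bins) {
  p <- ggplot2::ggplot(
    bins,
    ggplot2::aes(x = .data$bin_lower + 0.05, y = .data$rel_freq)
  ) +
    ggplot2::geom_col(width = 0.09) +
    ggplot2::scale_x_continuous(breaks = seq(0, 1, 0.1), limits = c(0, 1)) +
    ggplot2::labs(x = expression(H^2), y = "relative frequency") +
    ggplot2::theme_minimal()
  if ("molecular_class" %in% names(bins)) {
    p <- p + ggplot2::facet_wrap(~molecular_class)
  }
  p
}

#' Plot the threshold-stability scan
#'
#' The four global network properties against the p-value grid, one line per
#' candidate correlation cutoff; a stable candidate shows four flat lines.
#'
#' @param object A `threshold_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_calibration
#' @export
autoplot.threshold_calibration <- function(object, ...) {
  object$scan |>
    tidyr::pivot_longer(c("avg_degree", "clustering", "density", "diameter"),
                        names_to = "property") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$p, y = .data$value,
                                 colour = factor(.data$candidate),
                                 group = .data$candidate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(colour = "candidate |rho| cutoff", x = "p-value threshold",
                  y = NULL) +
    ggplot2::theme_minimal()
}
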