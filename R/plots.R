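#' Plot a signed sociogram
#'
#' Draws the network with a deterministic force-directed layout: edge width
#' proportional to the SR-based weight, solid lines for two-way (both
#' directions significant) and dashed for one-way edges.
#'
#' @param object A `"social_graph"`.
#' @param layout_seed Seed for the layout so plots are reproducible.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.social_graph <- function(object, layout_seed = 42, ...) {
  gr <- object$graph
  old <- if (exists(".Random.seed", .GlobalEnv)) .Random.seed else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(gr)
  nodes <- tibble::tibble(id = igraph::V(gr)$name,
                          x = xy[, 1], y = xy[, 2])
  el <- igraph::as_edgelist(gr)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(el) > 0) {
    edges <- tibble::tibble(
      x = nodes$x[match(el[, 1], nodes$id)],
      y = nodes$y[match(el[, 1], nodes$id)],
      xend = nodes$x[match(el[, 2], nodes$id)],
      yend = nodes$y[match(el[, 2], nodes$id)],
      weight = igraph::E(gr)$weight %||% rep(1, nrow(el)),
      direction = igraph::E(gr)$direction %||% rep("two-way", nrow(el)))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight,
                   linetype = .data$direction),
      color = if (object$sign == "positive") "steelblue" else "firebrick") +
      ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none")
  }
  p +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id),
                       hjust = -0.25, vjust = -0.25, size = 3) +
    ggplot2::labs(title = sprintf("%s network", object$sign)) +
    ggplot2::theme_void()
}

#' Plot a day-to-day stability series
#'
#' Consecutive-day Mantel correlations over the trial, with the mean
#' consecutive correlation (the stability summary) as a horizontal line.
#'
#' @param object A `"stability_series"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_series <- function(object, ...) {
  series <- object$series
  series$pair <- paste0(series$day_from, "~", series$day_to)
  series$pair <- factor(series$pair, levels = series$pair)
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$pair, y = .data$r, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_consecutive_r,
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "day pair", y = "Mantel r",
                  title = sprintf("Network stability (mean r = %.2f)",
                                  object$mean_consecutive_r)) +
    ggplot2::theme_minimal()
}
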