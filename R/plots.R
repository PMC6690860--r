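#' Plot a frequency series
#' @param x a [frequency_series()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.frequency_series <- function(x, ...) {
  graphics::plot(x$year, x$frequency, type = "b", pch = 16,
                 xlab = "year", ylab = "relative frequency",
                 main = attr(x, "word"), ...)
  if (attr(x, "smooth") > 0L) {
    graphics::lines(x$year, x$smoothed, col = "steelblue", lwd = 2)
  }
  invisible(x)
}

#' Plot a 2-D semantic drift trajectory
#'
#' Anchors (modern-sense synonyms of the start- and end-year meanings) are
#' drawn as labelled points; the word's aligned historical positions are
#' joined in year order.
#'
#' @param x a [drift_trajectory()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drift_trajectory <- function(x, ...) {
  xs <- c(x$waypoints$x, x$anchors$x)
  ys <- c(x$waypoints$y, x$anchors$y)
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = sprintf("PC1 (%.0f%%)", 100 * x$pca_explained[1]),
                 ylab = sprintf("PC2 (%.0f%%)", 100 * x$pca_explained[2]),
                 main = sprintf("semantic drift of '%s'", x$word), ...)
  cols <- c(start = "firebrick", end = "forestgreen", both = "purple")
  graphics::points(x$anchors$x, x$anchors$y, pch = 4,
                   col = cols[x$anchors$epoch])
  graphics::text(x$anchors$x, x$anchors$y, x$anchors$word, pos = 3,
                 cex = 0.7, col = cols[x$anchors$epoch])
  graphics::lines(x$waypoints$x, x$waypoints$y, col = "gray40")
  graphics::points(x$waypoints$x, x$waypoints$y, pch = 16)
  graphics::text(x$waypoints$x, x$waypoints$y, x$waypoints$year, pos = 1,
                 cex = 0.7)
  invisible(x)
}

#' Plot a semantic network
#' @param x a `semantic_network`.
#' @param ... passed to the igraph plot method.
#' @export
plot.semantic_network <- function(x, ...) {
  g <- x$graph
  if (igraph::vcount(g) == 0L) {
    graphics::plot.new()
    graphics::title(main = "empty network")
    return(invisible(x))
  }
  memb <- x$communities[igraph::V(g)$name]
  igraph::plot.igraph(g, vertex.color = memb,
                      vertex.label = igraph::V(g)$name, ...)
  invisible(x)
}
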