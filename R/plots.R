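#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot takeover samples and goodness-of-fit overlays
#'
#' `autoplot()` on a `takeover_samples` tibble draws the histogram of raw
#' takeover times; on a `takeover_gof` it draws the normalized histogram
#' (density scale, `ceiling(2 * n^(1/3))` bins) with the target density
#' overlaid — the standard histogram-vs-curve view of the limit laws.
#' `plot_snapshot()` renders a 2D lattice state as a tile map (infected
#' cells dark), the usual way of looking at the growing cluster.
#'
#' @param object A `takeover_samples` or `takeover_gof` object.
#' @param infected Logical membership vector (see [takeover_state()]).
#' @param graph A 2D `graph_lattice()` graph.
#' @param ... Unused.
#' @return A ggplot object.
#' @name takeover-plots
NULL

n_bins <- function(n) max(1L, ceiling(2 * n^(1 / 3)))

#' @rdname takeover-plots
#' @method autoplot takeover_samples
#' @export
autoplot.takeover_samples <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_histogram(bins = n_bins(nrow(object)),
                            fill = "grey30", color = "white") +
    ggplot2::labs(
      x = "takeover time (steps)", y = "count",
      title = sprintf("Takeover times: %s", attr(object, "topology") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname takeover-plots
#' @method autoplot takeover_gof
#' @export
autoplot.takeover_gof <- function(object, ...) {
  z <- object$z
  df <- tibble(z = z)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            bins = n_bins(length(z)),
                            fill = "grey70", color = "white")
  grid <- seq(min(z), max(z), length.out = 512)
  dens <- if (is.numeric(object$target)) {
    stats::density(object$target, from = min(z), to = max(z), n = 512)$y
  } else if (object$target$kind == "f_prime") {
    stats::density(model_sample(object$target, 1e5),
                   from = min(z), to = max(z), n = 512)$y
  } else {
    model_pdf(object$target, grid)
  }
  p +
    ggplot2::geom_line(data = tibble(x = grid, y = dens),
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.9) +
    ggplot2::labs(x = "normalized takeover time", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname takeover-plots
#' @export
plot_snapshot <- function(infected, graph) {
  grid <- snapshot_grid(infected, graph)
  if (length(dim(grid)) != 2L) abort("plot_snapshot() draws 2D lattices only")
  n <- dim(grid)[1]
  df <- tibble(
    x = rep(seq_len(n), times = n),
    y = rep(seq_len(n), each = n),
    state = factor(as.vector(grid), levels = c(0, 1),
                   labels = c("susceptible", "infected"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(susceptible = "grey80",
                                          infected = "black")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
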