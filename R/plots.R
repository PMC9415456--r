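#' Plot an abundance time series
#'
#' Points are the per-group posterior point estimates; vertical lines the
#' log-normal intervals.
#'
#' @param object An `abundance_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.abundance_series <- function(object, ...) {
  lev <- attr(object, "level") %||% 0.95
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(x = NULL, y = "Abundance",
                  title = sprintf("Abundance with %g%% log-normal intervals",
                                  100 * lev)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted detection function
#'
#' Histogram of the observed (in-truncation) perpendicular distances with
#' the fitted average detection curve overlaid, scaled as a detection
#' probability.
#'
#' @param object A `det_fn` with stored distances.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.det_fn <- function(object, bins = 20, ...) {
  w <- object$truncation
  xs <- seq(0, w, length.out = 200)
  sig <- exp(object$theta[1])  # curve at covariate reference level
  # fitted conditional density of detected distances at the reference level
  curve_df <- tibble::tibble(x = xs,
                             f = exp(-xs^2 / (2 * sig^2)) / hn_integral(sig, w))
  dist_df <- tibble::tibble(distance = object$distances)
  ggplot2::ggplot(dist_df, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(x = .data$x, y = .data$f),
                       colour = "steelblue", linewidth = 1) +
    ggplot2::labs(x = "Perpendicular distance", y = "Density",
                  title = "Half-normal detection function") +
    ggplot2::theme_minimal()
}

#' Map a per-cell summary over the prediction grid
#'
#' Joins a per-cell summary (from [summarize_cells()]) back onto cell
#' coordinates and draws a raster map of the chosen statistic.
#'
#' @param map Output of [summarize_cells()].
#' @param grids The prediction-grid tibble (coordinates are taken from the
#'   first period each cell appears in).
#' @param stat Column of `map` to plot (`"mean"` or `"se"`).
#' @return A ggplot.
#' @export
plot_cell_map <- function(map, grids, stat = c("mean", "se")) {
  stat <- match.arg(stat)
  coords <- grids |>
    dplyr::distinct(.data$cell_id, .keep_all = TRUE) |>
    dplyr::select("cell_id", "x", "y")
  df <- dplyr::left_join(map, coords, by = "cell_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data[[stat]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = stat, title = sprintf("Per-cell %s abundance", stat)) +
    ggplot2::theme_minimal()
  if ("group" %in% names(df)) p <- p + ggplot2::facet_wrap(~group)
  p
}
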