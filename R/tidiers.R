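# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' Tidy an occupancy solution
#'
#' @param x an `occupancy_solution`.
#' @param ... unused.
#' @return tibble with one row per candidate: index, weight, selected flag.
#' @exportS3Method generics::tidy
tidy.occupancy_solution <- function(x, ...) {
  tibble::tibble(candidate = seq_along(x$weights),
                 weight = x$weights,
                 selected = x$weights > 0)
}

#' One-row summary of an occupancy solution
#'
#' @param x an `occupancy_solution`.
#' @param ... unused.
#' @return tibble: selected count, threshold, occupancy sum, residual sum of
#'   squares, solver provenance.
#' @exportS3Method generics::glance
glance.occupancy_solution <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$weights),
                 n_selected = sum(x$weights > 0),
                 threshold = x$threshold,
                 occupancy_sum = sum(x$weights),
                 rss = x$objective,
                 provenance = x$provenance)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Resolution sweep plot for a flip benchmark
#'
#' Success (flip recovered at any mainchain amplitude) and false-positive
#' rates against resolution.
#'
#' @param object a `flip_benchmark` from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.flip_benchmark <- function(object, ...) {
  sm <- summarize_benchmark(object)
  fp <- dplyr::summarise(
    dplyr::group_by(object, .data$resolution),
    fp_rate = 100 * sum(.data$flip_fp) / sum(.data$n_residues),
    .groups = "drop")
  df <- dplyr::left_join(sm$by_resolution, fp, by = "resolution")
  long <- tibble::tibble(
    resolution = rep(df$resolution, 2),
    rate = c(df$success_rate, df$fp_rate),
    metric = rep(c("flip true positives", "flip false positives"),
                 each = nrow(df)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$resolution, y = .data$rate,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c("flip true positives" = "#1b9e77",
                                            "flip false positives" = "#d95f02")) +
    ggplot2::labs(x = "simulated resolution (Å)", y = "rate (%)",
                  colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Map slice plot
#'
#' Plots one z-section of a density map, optionally overlaying atom
#' positions close to the slice.
#'
#' @param map a [density_map()].
#' @param z Cartesian z of the slice (nearest grid plane used).
#' @param model optional [protein_model()] whose atoms within 1 A of the
#'   slice are overplotted.
#' @return a ggplot object.
#' @export
plot_map_slice <- function(map, z = NULL, model = NULL) {
  zc <- map_axis_coords(map, 3)
  if (is.null(z)) z <- zc[ceiling(length(zc) / 2)]
  k <- which.min(abs(zc - z))
  sl <- map$values[, , k]
  df <- expand.grid(x = map_axis_coords(map, 1), y = map_axis_coords(map, 2))
  df$density <- as.numeric(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = sprintf("map slice at z = %.2f Å", zc[k])) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    at <- model$atoms[abs(model$atoms$z - zc[k]) < 1, ]
    if (nrow(at) > 0) {
      p <- p + ggplot2::geom_point(
        data = at, ggplot2::aes(x = .data$x, y = .data$y),
        inherit.aes = FALSE, shape = 3, colour = "white")
    }
  }
  p
}
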