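#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a road density profile
#'
#' Density along the route, with an optional significance threshold overlay.
#'
#' @param object a `density_profile` from [kde_profile()].
#' @param threshold optional tibble from [significance_threshold()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.density_profile <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$s, y = .data$density)) +
    ggplot2::geom_line(color = "steelblue4") +
    ggplot2::labs(x = "Measure along route (m)",
                  y = "Encounter density (events / m)",
                  title = sprintf("Network KDE profile (h = %g m, n = %d)",
                                  attr(object, "h"), attr(object, "n_events"))) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_line(
      data = threshold, ggplot2::aes(y = .data$threshold),
      linetype = "dashed", color = "firebrick")
  }
  p
}

#' Plot a raster grid
#'
#' Cell map of a [raster_grid()] in projected coordinates. Categorical grids
#' (few unique values) are drawn with a discrete fill.
#'
#' @param object a [raster_grid()].
#' @param discrete force discrete fill; default auto (<= 12 unique values).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, discrete = NULL, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object$values)),
                           col = seq_len(ncol(object$values)))
  ctr <- cell_center(object, df$row, df$col)
  df$x <- ctr[, 1]; df$y <- ctr[, 2]
  df$value <- object$values[cbind(df$row, df$col)]
  vals <- unique(df$value[!is.na(df$value)])
  if (is.null(discrete)) discrete <- length(vals) <= 12
  if (discrete) df$value <- factor(df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map hotspots, roads and least-cost paths
#'
#' Overview map of the analysis outputs: the road network, detected hotspot
#' intervals (scaled by cluster strength), and optionally LCP polylines.
#'
#' @param hotspots hotspot tibble from [find_hotspots()].
#' @param network a `road_network`.
#' @param lcps optional LCP tibble from [connect_nodes()].
#' @return A ggplot.
#' @export
plot_hotspot_map <- function(hotspots, network, lcps = NULL) {
  road_df <- purrr::map2(network$routes$route_id, network$routes$geometry,
                         ~ tibble::tibble(route_id = .x, x = .y[, 1],
                                          y = .y[, 2])) |>
    dplyr::bind_rows()
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = road_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$route_id),
                       color = "grey40", linewidth = 0.4)
  if (!is.null(lcps) && nrow(lcps) > 0) {
    lcp_df <- purrr::imap(lcps$path, ~ tibble::tibble(
      lcp = .y, x = .x[, 1], y = .x[, 2])) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_path(
      data = lcp_df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$lcp),
      color = "darkgreen", linewidth = 0.5, alpha = 0.8)
  }
  if (nrow(hotspots) > 0) {
    hot_df <- purrr::map(seq_len(nrow(hotspots)), function(i) {
      sub <- route_subline(network, hotspots$route_id[i], hotspots$start[i],
                           hotspots$end[i])
      tibble::tibble(hotspot = i, strength = hotspots$strength[i],
                     x = sub[, 1], y = sub[, 2])
    }) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_path(
      data = hot_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$hotspot,
                   linewidth = .data$strength),
      color = "firebrick") +
      ggplot2::scale_linewidth(range = c(0.8, 2.2))
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", linewidth = "Cluster strength") +
    ggplot2::theme_minimal()
}
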