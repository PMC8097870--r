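#' Plot an analyte map as a ggplot raster
#'
#' @param map An [analyte_map()] or [ratio_map()].
#' @param ... Unused.
#' @export
plot_analyte_map <- function(map, ...) {
  df <- tidy(map)
  lab <- if (inherits(map, "analyte_map") && map$analyte == "O2") {
    "pO2 (% air sat)"
  } else if (inherits(map, "analyte_map")) "pH" else "ratio"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey60") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot an ROI time series with its fitted linear range
#'
#' @param ts A time-series tibble (from [extract_roi_timeseries()] or
#'   [timeseries()]).
#' @param fit Optional `linear_fit` whose window and line are overlaid.
#' @export
plot_timeseries <- function(ts, fit = NULL) {
  p <- ggplot2::ggplot(ts, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (s)", y = "value") +
    ggplot2::theme_classic()
  if (!is.null(fit)) {
    seg <- tibble(x = fit$window_start_s, xend = fit$window_end_s,
                  y = fit$intercept + fit$slope * fit$window_start_s,
                  yend = fit$intercept + fit$slope * fit$window_end_s)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend,
                   y = .data$y, yend = .data$yend),
      colour = "red", linewidth = 0.8, inherit.aes = FALSE)
  }
  p
}

#' @method autoplot analyte_map
#' @export
autoplot.analyte_map <- function(object, ...) plot_analyte_map(object, ...)

#' @method autoplot ratio_map
#' @export
autoplot.ratio_map <- function(object, ...) plot_analyte_map(object, ...)

#' @method autoplot roi_timeseries
#' @export
autoplot.roi_timeseries <- function(object, ...) plot_timeseries(object, ...)
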