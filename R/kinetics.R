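#' Build a measurement time series
#'
#' @param time_s Strictly increasing times in seconds.
#' @param value Analyte values (% air saturation or pH).
#' @param gap Optional logical vector flagging unusable timepoints.
#' @param analyte Optional label (`"O2"` or `"pH"`).
#' @return Tibble with class `roi_timeseries`.
#' @export
timeseries <- function(time_s, value, gap = FALSE, analyte = NULL) {
  if (length(time_s) != length(value)) abort("lengths differ")
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    abort("`time_s` must be strictly increasing")
  }
  out <- tibble(time_s = as.numeric(time_s), value = as.numeric(value),
                gap = rep_len(gap, length(time_s)) & TRUE)
  if (!is.null(analyte)) attr(out, "analyte") <- analyte
  class(out) <- c("roi_timeseries", class(out))
  out
}

#' Read / write time-series CSV
#'
#' CSV contract: columns `time_s,value[,gap]`.
#' @param path File path.
#' @export
read_timeseries_csv <- function(path) {
  df <- utils::read.csv(path)
  timeseries(df$time_s, df$value, gap = df$gap %||% FALSE)
}

#' @rdname read_timeseries_csv
#' @param ts A time-series tibble.
#' @export
write_timeseries_csv <- function(ts, path) {
  cols <- intersect(c("time_s", "value", "n_valid", "gap"), names(ts))
  utils::write.csv(as.data.frame(ts)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# drop gap rows, keep original sample positions
nongap <- function(ts) {
  gap <- if ("gap" %in% names(ts)) ts$gap | !is.finite(ts$value) else !is.finite(ts$value)
  ts[!gap, , drop = FALSE]
}

# O(1)-per-window OLS statistics from prefix sums
window_ols <- function(cs, i, j) {
  n <- j - i + 1
  sx <- cs$x[j + 1L] - cs$x[i]
  sy <- cs$y[j + 1L] - cs$y[i]
  sxx <- cs$xx[j + 1L] - cs$xx[i]
  syy <- cs$yy[j + 1L] - cs$yy[i]
  sxy <- cs$xy[j + 1L] - cs$xy[i]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy <- sxy - sx * sy / n
  slope <- if (vx > 0) cxy / vx else NA_real_
  r2 <- if (vx > 0 && vy > 0) (cxy^2) / (vx * vy) else 0
  list(slope = slope, intercept = sy / n - (slope %||% 0) * sx / n,
       r2 = r2, n = n, degenerate = vy <= 0)
}

prefix_sums <- function(x, y) {
  list(x = c(0, cumsum(x)), y = c(0, cumsum(y)),
       xx = c(0, cumsum(x^2)), yy = c(0, cumsum(y^2)),
       xy = c(0, cumsum(x * y)))
}

#' Find the linear range of a depletion curve
#'
#' Among all contiguous windows of length at least
#' `max(min_points, min_fraction * T)` whose ordinary-least-squares r-squared
#' meets `r2_threshold`, returns the longest (earliest start on ties). If no
#' window qualifies, returns the minimum-length window maximising r-squared,
#' flagged `sub_threshold`.
#'
#' @param ts Time series (tibble with `time_s`, `value`, optional `gap`);
#'   gap rows are excluded before windowing.
#' @param r2_threshold Minimum r-squared (default 0.99).
#' @param min_fraction Minimum window length as a fraction of the series
#'   length (default 0.3).
#' @param min_points Absolute minimum window length (default 10).
#' @return A `linear_window`: list with `start`, `end` (inclusive indices
#'   into the gap-filtered series), `r2`, `sub_threshold`.
#' @export
find_linear_range <- function(ts, r2_threshold = 0.99, min_fraction = 0.3,
                              min_points = 10L) {
  ts <- nongap(ts)
  t_len <- nrow(ts)
  if (t_len < min_points) {
    abort(sprintf("need >= %d non-gap samples, got %d", min_points, t_len))
  }
  l_min <- max(min_points, ceiling(min_fraction * t_len))
  cs <- prefix_sums(ts$time_s, ts$value)
  for (len in seq(t_len, l_min)) {
    for (start in seq_len(t_len - len + 1L)) {
      w <- window_ols(cs, start, start + len - 1L)
      if (w$r2 >= r2_threshold) {
        return(structure(list(start = start, end = start + len - 1L,
                              r2 = w$r2, sub_threshold = FALSE),
                         class = "linear_window"))
      }
    }
  }
  # fall back: best r2 at minimum length, earliest on ties
  best <- NULL
  for (start in seq_len(t_len - l_min + 1L)) {
    w <- window_ols(cs, start, start + l_min - 1L)
    if (is.null(best) || w$r2 > best$r2 + 1e-15) {
      best <- list(start = start, end = start + l_min - 1L, r2 = w$r2)
    }
  }
  structure(c(best, list(sub_threshold = TRUE)), class = "linear_window")
}

#' Fit a straight line to (a window of) a time series
#'
#' Closed-form ordinary least squares of value on time. A zero-variance
#' (constant) series gets slope 0 and r-squared 0 by convention, flagged
#' `degenerate`.
#'
#' @param ts Time series tibble (gap rows excluded first).
#' @param window Optional `linear_window` from [find_linear_range()] (or a
#'   2-vector of inclusive indices); default is the full series.
#' @return A `linear_fit` with `slope` (analyte units per second),
#'   `intercept`, `r2`, `window`, `n`.
#' @export
fit_slope <- function(ts, window = NULL) {
  ts <- nongap(ts)
  if (is.null(window)) {
    i <- 1L; j <- nrow(ts); sub <- FALSE
  } else if (inherits(window, "linear_window")) {
    i <- window$start; j <- window$end; sub <- window$sub_threshold
  } else {
    i <- window[1L]; j <- window[2L]; sub <- FALSE
  }
  if (j - i + 1L < 2L) abort("window must contain >= 2 points")
  if (i < 1L || j > nrow(ts)) abort("window out of range")
  cs <- prefix_sums(ts$time_s, ts$value)
  w <- window_ols(cs, i, j)
  structure(list(slope = if (w$degenerate) 0 else w$slope,
                 intercept = w$intercept, r2 = w$r2,
                 window = c(i, j), n = w$n,
                 window_start_s = ts$time_s[i], window_end_s = ts$time_s[j],
                 degenerate = w$degenerate, sub_threshold = sub),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit slope = %.4g /s, r2 = %.4f, n = %d [%g, %g] s%s>\n",
              x$slope, x$r2, x$n, x$window_start_s, x$window_end_s,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' @method tidy linear_fit
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope, x$intercept))
}

#' @method glance linear_fit
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(r.squared = x$r2, n = x$n,
         window_start_s = x$window_start_s, window_end_s = x$window_end_s,
         degenerate = x$degenerate, sub_threshold = x$sub_threshold)
}

#' Cell-number-normalised OCR / ECAR from a fitted slope
#'
#' Sign convention: consumption (falling pO2) and acidification (falling pH)
#' give positive normalised rates. For OCR the raw slope is in % air
#' saturation per second and the normalised rate is
#' `(-slope / cell_count) * 1e7`. For ECAR the fitted pH/s slope is first
#' converted to mpH/min (x 60,000) and the normalised rate is
#' `(-slope_mpH_min / cell_count) * 1e4`. A rising signal yields a negative
#' normalised rate with a warning.
#'
#' @param fit A `linear_fit` (slope in %O2/s for OCR, pH/s for ECAR).
#' @param cell_count Positive cell count used for normalisation.
#' @param kind `"OCR"` or `"ECAR"`.
#' @return One-row tibble (class `rate_result`): `kind`, `raw_slope`,
#'   `units`, `cell_count`, `normalized_rate`, window and fit quality.
#' @examples
#' fit <- fit_slope(timeseries(c(0, 10, 20), c(10, 9, 8)))
#' normalize_rate(fit, 45000, "OCR")  # slope -0.1 %O2/s
#' @export
normalize_rate <- function(fit, cell_count, kind = c("OCR", "ECAR")) {
  kind <- match.arg(kind)
  stopifnot(inherits(fit, "linear_fit"))
  if (!is.numeric(cell_count) || length(cell_count) != 1L || cell_count <= 0) {
    abort("`cell_count` must be a positive number")
  }
  if (kind == "OCR") {
    raw <- fit$slope          # %O2/s
    units <- "%O2/s"
    normalized <- (-raw / cell_count) * 1e7
  } else {
    raw <- fit$slope * 60000  # pH/s -> mpH/min
    units <- "mpH/min"
    normalized <- (-raw / cell_count) * 1e4
  }
  if (normalized < 0) {
    warn(sprintf("increasing %s signal: negative normalised rate", kind))
  }
  out <- tibble(kind = kind, raw_slope = raw, units = units,
                window_start_s = fit$window_start_s,
                window_end_s = fit$window_end_s, r2 = fit$r2,
                cell_count = as.integer(round(cell_count)),
                normalized_rate = normalized)
  class(out) <- c("rate_result", class(out))
  out
}

#' Write a rates table as CSV
#'
#' CSV contract: header
#' `roi,kind,raw_slope,units,window_start_s,window_end_s,r2,cell_count,normalized_rate`.
#' @param rates Tibble of [normalize_rate()] rows (with an `roi` column).
#' @param path File path.
#' @export
write_rates_csv <- function(rates, path) {
  cols <- c("roi", "kind", "raw_slope", "units", "window_start_s",
            "window_end_s", "r2", "cell_count", "normalized_rate")
  utils::write.csv(as.data.frame(rates)[, intersect(cols, names(rates))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
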