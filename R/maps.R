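# lightweight S3 containers for per-pixel maps

#' Construct an analyte map
#'
#' @param values Numeric matrix of calibrated analyte values.
#' @param analyte `"O2"` (% air saturation) or `"pH"`.
#' @param pixel_size_mm Pixel edge length in mm.
#' @param timestamp_s Acquisition time in seconds.
#' @param flags Integer matrix of per-pixel flags (0 ok, 1 clamped, 2 invalid);
#'   defaults to invalid where `values` is not finite.
#' @export
analyte_map <- function(values, analyte = c("O2", "pH"), pixel_size_mm,
                        timestamp_s = 0, flags = NULL) {
  analyte <- match.arg(analyte)
  stopifnot(is.matrix(values))
  if (is.null(flags)) {
    flags <- matrix(FLAG_OK, nrow(values), ncol(values))
    flags[!is.finite(values)] <- FLAG_INVALID
  }
  structure(list(values = values, analyte = analyte,
                 pixel_size_mm = pixel_size_mm, timestamp_s = timestamp_s,
                 flags = flags),
            class = "analyte_map")
}

#' Construct a ratio map
#'
#' @param values Numeric matrix of sensitive/reference intensity ratios,
#'   `NaN` at invalid pixels.
#' @inheritParams analyte_map
#' @export
ratio_map <- function(values, pixel_size_mm, timestamp_s = 0, flags = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(flags)) {
    flags <- matrix(FLAG_OK, nrow(values), ncol(values))
    flags[!is.finite(values)] <- FLAG_INVALID
  }
  structure(list(values = values, pixel_size_mm = pixel_size_mm,
                 timestamp_s = timestamp_s, flags = flags),
            class = "ratio_map")
}

#' @export
print.analyte_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<analyte_map %s %dx%d t=%gs range [%.3g, %.3g]>\n",
              x$analyte, nrow(x$values), ncol(x$values), x$timestamp_s,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.ratio_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<ratio_map %dx%d t=%gs range [%.3g, %.3g]>\n",
              nrow(x$values), ncol(x$values), x$timestamp_s,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Tidy a map into a long tibble of pixels
#'
#' @param x An [analyte_map()] or [ratio_map()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `value`, `flag`.
#' @method tidy analyte_map
#' @export
tidy.analyte_map <- function(x, ...) {
  tibble(row = rep(seq_len(nrow(x$values)), times = ncol(x$values)),
         col = rep(seq_len(ncol(x$values)), each = nrow(x$values)),
         value = as.vector(x$values), flag = as.vector(x$flags))
}

#' @rdname tidy.analyte_map
#' @method tidy ratio_map
#' @export
tidy.ratio_map <- tidy.analyte_map
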