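#' Per-pixel sensitive/reference ratio of one frame
#'
#' Ratiometric readout: dividing the analyte-sensitive channel by the
#' reference channel cancels common-mode illumination and dye-loading
#' variation. Pixels whose reference intensity falls below the division
#' guard `eps` become `NaN` with an invalid flag.
#'
#' @param stack A [frame_stack()].
#' @param t_index Frame index (1-based).
#' @param eps Division guard; default 1% of the reference channel's dynamic
#'   range across the stack.
#' @return A [ratio_map()].
#' @export
compute_ratio <- function(stack, t_index, eps = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (t_index < 1L || t_index > d[1L]) abort("`t_index` out of range")
  si <- stack$channel_roles[["sensitive"]]
  ri <- stack$channel_roles[["reference"]]
  ref_all <- stack$frames[, , , ri]
  if (is.null(eps)) {
    dr <- max(ref_all) - min(ref_all)
    eps <- if (dr > 0) 0.01 * dr else 1e-12
  }
  sens <- matrix(stack$frames[t_index, , , si], d[2L], d[3L])
  ref <- matrix(stack$frames[t_index, , , ri], d[2L], d[3L])
  vals <- sens / ref
  invalid <- ref < eps
  vals[invalid] <- NaN
  flags <- matrix(FLAG_OK, d[2L], d[3L])
  flags[invalid] <- FLAG_INVALID
  ratio_map(vals, stack$pixel_size_mm, stack$timestamps_s[t_index], flags)
}

#' Noise-filter a map by Gaussian smoothing
#'
#' Gaussian blur with sigma = `smoothing_factor` pixels, as a normalised
#' convolution: invalid (`NaN`) pixels carry zero weight, so valid
#' neighbourhood means are preserved near gaps. A factor of 0 is the
#' identity. Smoothing is intended to run on ratio maps, before calibration
#' inversion.
#'
#' @param map A [ratio_map()] or [analyte_map()].
#' @param smoothing_factor Gaussian sigma in pixels (>= 0). The instrument
#'   convention "smoothing factor 2" corresponds to sigma = 2 px.
#' @return A map of the same class.
#' @export
smooth_map <- function(map, smoothing_factor) {
  if (!is.numeric(smoothing_factor) || smoothing_factor < 0) {
    abort("`smoothing_factor` must be >= 0")
  }
  if (smoothing_factor == 0) return(map)
  out <- map
  out$values <- nan_aware_blur(map$values, smoothing_factor)
  out$flags[!is.finite(out$values)] <- FLAG_INVALID
  out
}

#' Convert a ratio map into a calibrated analyte map
#'
#' Applies the inverse calibration model per pixel. `NaN` pixels and
#' out-of-range clamps are recorded in the flag matrix.
#'
#' @param map A [ratio_map()].
#' @param cal A fitted `o2_calibration` or `ph_calibration`.
#' @param batch_id Optional batch of the stack; mismatch with the
#'   calibration's batch raises a warning.
#' @return An [analyte_map()].
#' @export
apply_calibration <- function(map, cal, batch_id = NULL) {
  stopifnot(inherits(map, "ratio_map"))
  if (!is.null(batch_id) && nzchar(cal$batch_id) && !identical(batch_id, cal$batch_id)) {
    warn(sprintf("calibration batch '%s' does not match stack batch '%s'",
                 cal$batch_id, batch_id))
  }
  inv <- invert_ratio(map$values, cal)
  inv$flags[map$flags == FLAG_INVALID] <- FLAG_INVALID
  analyte_map(inv$values,
              analyte = if (inherits(cal, "o2_calibration")) "O2" else "pH",
              pixel_size_mm = map$pixel_size_mm,
              timestamp_s = map$timestamp_s, flags = inv$flags)
}

#' Fit a one-point adjustment (OPA) illumination field
#'
#' From an image of a plate holding the same analyte value everywhere, fits
#' the multiplicative correction that removes uneven illumination: in pixel
#' mode one factor per pixel (`expected / observed`, in ratio space); in
#' plate mode one scalar per well from the well-mean.
#'
#' @param uniform_map A [ratio_map()] (or [analyte_map()]) of the uniform
#'   plate.
#' @param expected_value The true uniform value (same space as the map).
#' @param layout Optional [plate_layout()]; switches to per-well mode.
#' @return An `illumination_field`.
#' @export
fit_illumination <- function(uniform_map, expected_value, layout = NULL) {
  v <- uniform_map$values
  if (is.null(layout)) {
    if (any(v <= 0, na.rm = TRUE)) abort("observed values must be > 0")
    corr <- expected_value / v
    corr[!is.finite(corr)] <- NA_real_
  } else {
    wells <- extract_wells_values(v, layout)
    if (any(wells <= 0, na.rm = TRUE)) abort("observed well means must be > 0")
    corr <- expected_value / wells
  }
  med <- median(corr, na.rm = TRUE)
  if (!is.finite(med) || med < 0.5 || med > 2) {
    abort(sprintf("median correction factor %.3g outside the [0.5, 2] sanity band", med))
  }
  structure(list(correction = corr, mode = if (is.null(layout)) "pixel" else "plate",
                 layout = layout, reference_value = expected_value),
            class = "illumination_field")
}

#' Apply a one-point adjustment to a map
#'
#' Multiplicative correction in ratio space; the fixed pipeline order is
#' ratio -> OPA -> smooth -> calibrate.
#'
#' @param map A [ratio_map()] (or [analyte_map()] in plate workflows).
#' @param field An `illumination_field` from [fit_illumination()].
#' @return The corrected map (same class).
#' @export
apply_opa <- function(map, field) {
  stopifnot(inherits(field, "illumination_field"))
  out <- map
  if (field$mode == "pixel") {
    if (!all(dim(field$correction) == dim(map$values))) {
      abort("illumination field shape does not match the map")
    }
    out$values <- map$values * field$correction
  } else {
    lay <- field$layout
    for (w in seq_len(nrow(lay$centers))) {
      disc <- well_disc_mask(dim(map$values), lay$centers$y_px[w],
                             lay$centers$x_px[w], lay$radius_px)
      out$values[disc] <- map$values[disc] * field$correction[w]
    }
  }
  out$flags[!is.finite(out$values)] <- FLAG_INVALID
  out
}

#' Extract an ROI-mean time series from a sequence of maps
#'
#' One value per timestamp: the mean over valid (finite, unflagged-invalid)
#' ROI pixels. Timepoints whose valid fraction falls below
#' `min_valid_frac` are reported as gaps, not silently dropped.
#'
#' @param maps List of [analyte_map()]s (or [ratio_map()]s).
#' @param roi Logical matrix (the ROI mask, non-empty) or a [roi_mask()].
#' @param min_valid_frac Minimum fraction of valid ROI pixels for a
#'   timepoint to count (default 0.5).
#' @return Tibble `time_s`, `value`, `n_valid`, `gap` with class
#'   `roi_timeseries`.
#' @export
extract_roi_timeseries <- function(maps, roi, min_valid_frac = 0.5) {
  if (inherits(roi, "roi_mask")) roi <- roi$mask
  stopifnot(is.matrix(roi))
  roi <- roi & TRUE
  n_roi <- sum(roi)
  if (n_roi == 0L) abort("ROI mask is empty")
  rows <- purrr::map(maps, function(m) {
    if (!all(dim(m$values) == dim(roi))) abort("ROI shape does not match maps")
    v <- m$values[roi]
    ok <- is.finite(v) & (m$flags[roi] != FLAG_INVALID)
    n_valid <- sum(ok)
    tibble(time_s = m$timestamp_s,
           value = if (n_valid > 0L) mean(v[ok]) else NA_real_,
           n_valid = n_valid,
           gap = n_valid < min_valid_frac * n_roi)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("roi_timeseries", class(out))
  out
}

#' ROI mask container
#'
#' @param mask Non-empty logical matrix.
#' @param label Text label.
#' @export
roi_mask <- function(mask, label = "roi") {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE
  if (!any(mask)) abort("ROI mask is empty")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' Define a 96-well (or other) plate layout on the image grid
#'
#' @param n_rows,n_cols Plate format (8 x 12 for 96-well).
#' @param centers Tibble with `x_px`, `y_px` well centres in row-major
#'   A1..H12 order.
#' @param radius_px Extraction disc radius in pixels.
#' @param image_dim Optional `c(H, W)` to validate wells against.
#' @export
plate_layout <- function(n_rows, n_cols, centers, radius_px,
                         image_dim = NULL) {
  if (nrow(centers) != n_rows * n_cols) {
    abort("`centers` must have one row per well (row-major)")
  }
  if (!is.null(image_dim)) {
    if (any(centers$x_px - radius_px < 1 | centers$x_px + radius_px > image_dim[2L] |
            centers$y_px - radius_px < 1 | centers$y_px + radius_px > image_dim[1L])) {
      abort("well discs extend outside the image")
    }
  }
  dmin <- min(stats::dist(cbind(centers$x_px, centers$y_px)))
  if (dmin < 2 * radius_px) abort("well discs overlap")
  structure(list(n_rows = n_rows, n_cols = n_cols, centers = centers,
                 radius_px = radius_px,
                 well = well_names(n_rows, n_cols)),
            class = "plate_layout")
}

#' Regular-grid plate layout covering an image
#'
#' Convenience constructor: equally spaced well centres with disc radius a
#' fraction (default 80%) of half the pitch.
#'
#' @param image_dim `c(H, W)` in pixels.
#' @param n_rows,n_cols Plate format.
#' @param radius_frac Disc radius as a fraction of half the well pitch.
#' @export
grid_plate_layout <- function(image_dim, n_rows = 8, n_cols = 12,
                              radius_frac = 0.8) {
  pitch_y <- image_dim[1L] / n_rows
  pitch_x <- image_dim[2L] / n_cols
  centers <- tibble(
    x_px = rep((seq_len(n_cols) - 0.5) * pitch_x, times = n_rows),
    y_px = rep((seq_len(n_rows) - 0.5) * pitch_y, each = n_cols))
  radius <- radius_frac * min(pitch_x, pitch_y) / 2
  plate_layout(n_rows, n_cols, centers, radius, image_dim = image_dim)
}

well_disc_mask <- function(dims, yc, xc, radius) {
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  (rr - yc)^2 + (cc - xc)^2 <= radius^2
}

# per-well means of a raw value matrix (NaN-aware); internal
extract_wells_values <- function(values, layout) {
  vapply(seq_len(nrow(layout$centers)), function(w) {
    disc <- well_disc_mask(dim(values), layout$centers$y_px[w],
                           layout$centers$x_px[w], layout$radius_px)
    v <- values[disc]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
}

#' Per-well mean values of an analyte map
#'
#' Means over circular well discs, NaN-aware, in row-major A1..H12 order.
#' Wells whose disc is entirely invalid yield `NA` with `n_valid = 0`.
#'
#' @param map An [analyte_map()] (or [ratio_map()]).
#' @param layout A [plate_layout()].
#' @return Tibble `well`, `row`, `col`, `time_s`, `value`, `n_valid`.
#' @export
extract_wells <- function(map, layout) {
  stopifnot(inherits(layout, "plate_layout"))
  dims <- dim(map$values)
  if (any(layout$centers$x_px < 1 | layout$centers$x_px > dims[2L] |
          layout$centers$y_px < 1 | layout$centers$y_px > dims[1L])) {
    abort("plate layout lies outside the image")
  }
  rows <- lapply(seq_len(nrow(layout$centers)), function(w) {
    disc <- well_disc_mask(dims, layout$centers$y_px[w],
                           layout$centers$x_px[w], layout$radius_px)
    v <- map$values[disc]
    ok <- is.finite(v) & (map$flags[disc] != FLAG_INVALID)
    tibble(well = layout$well[w],
           row = ((w - 1L) %/% layout$n_cols) + 1L,
           col = ((w - 1L) %% layout$n_cols) + 1L,
           time_s = map$timestamp_s,
           value = if (any(ok)) mean(v[ok]) else NA_real_,
           n_valid = sum(ok))
  })
  dplyr::bind_rows(rows)
}

#' Write per-well values as CSV
#'
#' CSV contract: header `well,time_s,value,n_valid`.
#' @param wells Tibble from [extract_wells()].
#' @param path File path.
#' @export
write_wells_csv <- function(wells, path) {
  utils::write.csv(wells[, c("well", "time_s", "value", "n_valid")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ROI masks as 8-bit TIFF
#'
#' Nonzero pixels are inside the ROI.
#' @param path File path.
#' @param label Label for the returned [roi_mask()].
#' @export
read_roi_mask <- function(path, label = basename(path)) {
  roi_mask(tiff::readTIFF(path) > 0.5, label = label)
}

#' @rdname read_roi_mask
#' @param roi An [roi_mask()] or logical matrix.
#' @export
write_roi_mask <- function(roi, path) {
  m <- if (inherits(roi, "roi_mask")) roi$mask else roi & TRUE
  tiff::writeTIFF((m & TRUE) * 1, path, bits.per.sample = 8L)
  invisible(path)
}
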