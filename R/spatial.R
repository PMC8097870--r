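#' Detection parameters for metabolically active regions
#'
#' Detection works on the *depression* of the analyte below a robust
#' background estimate (median of pixels outside any supplied cell mask, or
#' the global median), because baseline pO2/pH drifts between wells; active
#' regions are found against the local background rather than at absolute
#' values.
#'
#' @param k Threshold in background MAD units (default 5); used when
#'   `threshold_abs` is `NULL`.
#' @param threshold_abs Optional absolute depression threshold (analyte
#'   units), overriding `k * MAD`.
#' @param min_area_mm2 Minimum region area retained (default 0.1 mm^2).
#' @param cell_mask Optional logical matrix; pixels inside it are excluded
#'   from the background estimate.
#' @export
detection_params <- function(k = 5, threshold_abs = NULL,
                             min_area_mm2 = 0.1, cell_mask = NULL) {
  assert_scalar_num(k, "k", 0, strict = TRUE)
  assert_scalar_num(min_area_mm2, "min_area_mm2", 0)
  structure(list(k = k, threshold_abs = threshold_abs,
                 min_area_mm2 = min_area_mm2, cell_mask = cell_mask),
            class = "detection_params")
}

#' Detect metabolically active regions in an analyte map
#'
#' Pixels whose depression (background minus value) exceeds the threshold
#' form the detection mask; its 8-connected components of at least
#' `min_area_mm2` are the regions. Labels are deterministic: numbered by
#' each region's first pixel in reading (row-major) order.
#'
#' @param map A calibrated (and typically smoothed) [analyte_map()].
#' @param params A [detection_params()].
#' @return A `region_set`: list with `labels` (integer matrix, 0 =
#'   background), `regions` (tibble `region_id`, `area_mm2`,
#'   `mean_depression`, `centroid_x`, `centroid_y`, `n_px`), plus the
#'   background estimate, MAD and threshold used.
#' @export
detect_active_regions <- function(map, params = detection_params()) {
  v <- map$values
  valid <- is.finite(v) & (map$flags != FLAG_INVALID)
  if (!any(valid)) abort("map has no valid pixels")
  bg_px <- valid
  if (!is.null(params$cell_mask)) bg_px <- bg_px & !params$cell_mask
  if (!any(bg_px)) bg_px <- valid
  bg <- median(v[bg_px])
  bg_mad <- mad(v[bg_px])
  thr <- params$threshold_abs %||% (params$k * bg_mad)
  depression <- bg - v
  mask <- valid & (depression > thr)
  labels <- label_components(mask, connectivity = 8)
  px_area <- map$pixel_size_mm^2
  n <- max(labels)
  regions <- NULL
  if (n > 0L) {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    rr <- ((idx - 1L) %% nrow(v)) + 1L
    cc <- ((idx - 1L) %/% nrow(v)) + 1L
    regions <- tibble(
      region_id = seq_len(n),
      n_px = tabulate(lab, n),
      area_mm2 = tabulate(lab, n) * px_area,
      mean_depression = vapply(split(depression[idx], lab), mean, numeric(1L)),
      centroid_x = vapply(split(cc, lab), mean, numeric(1L)),
      centroid_y = vapply(split(rr, lab), mean, numeric(1L)))
    keep <- regions$area_mm2 >= params$min_area_mm2
    # relabel surviving regions 1..m, preserving reading order
    new_labels <- matrix(0L, nrow(v), ncol(v))
    m <- 0L
    remap <- integer(n)
    for (id in regions$region_id[keep]) {
      m <- m + 1L
      remap[id] <- m
    }
    sel <- lab %in% regions$region_id[keep]
    new_labels[idx[sel]] <- remap[lab[sel]]
    labels <- new_labels
    regions <- regions[keep, , drop = FALSE]
    regions$region_id <- seq_len(nrow(regions))
  } else {
    regions <- tibble(region_id = integer(0), n_px = integer(0),
                      area_mm2 = numeric(0), mean_depression = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0))
  }
  structure(list(labels = labels, regions = regions, background = bg,
                 mad = bg_mad, threshold = thr,
                 pixel_size_mm = map$pixel_size_mm),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set %d regions, background %.4g, threshold %.4g>\n",
              nrow(x$regions), x$background, x$threshold))
  invisible(x)
}

#' Time to detection of a known cell region
#'
#' The first acquisition timestamp at which some detected region overlaps
#' the ground-truth mask with IoU at least `min_iou` (default 0.3), reported
#' in minutes; `NA` means not detected within the sequence.
#'
#' @param maps Time-ordered list of [analyte_map()]s.
#' @param truth_mask Logical matrix marking the true cell region.
#' @param params A [detection_params()].
#' @param min_iou Intersection-over-union acceptance level.
#' @return Minutes to first detection, or `NA_real_`.
#' @export
time_to_detection <- function(maps, truth_mask, params = detection_params(),
                              min_iou = 0.3) {
  truth_mask <- truth_mask & TRUE
  for (m in maps) {
    rs <- detect_active_regions(m, params)
    if (nrow(rs$regions) == 0L) next
    for (id in rs$regions$region_id) {
      if (iou(rs$labels == id, truth_mask) >= min_iou) {
        return(m$timestamp_s / 60)
      }
    }
  }
  NA_real_
}

#' Convert a cell count over an area into areal density
#'
#' @param cell_count Non-negative cell count.
#' @param area_cm2 Growth area in cm^2 (> 0).
#' @param rounding Presentation rounding: `"none"` or `"floor_thousand"`
#'   (floor to the next lower thousand). The mode used is recorded as an
#'   attribute of the result.
#' @return Cells/cm^2 (numeric scalar with attribute `rounding`).
#' @examples
#' areal_density(2000, 0.03, "floor_thousand")  # 66000
#' areal_density(6000, 0.03)                    # 200000
#' @export
areal_density <- function(cell_count, area_cm2,
                          rounding = c("none", "floor_thousand")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(cell_count) || cell_count < 0) abort("`cell_count` must be >= 0")
  assert_scalar_num(area_cm2, "area_cm2", 0, strict = TRUE)
  out <- cell_count / area_cm2
  if (rounding == "floor_thousand") out <- floor(out / 1000) * 1000
  attr(out, "rounding") <- rounding
  out
}

#' Write a region table as CSV
#'
#' CSV contract: header
#' `region_id,area_mm2,mean_depression,centroid_x,centroid_y`.
#' @param regions A `region_set` or its `regions` tibble.
#' @param path File path.
#' @export
write_regions_csv <- function(regions, path) {
  df <- if (inherits(regions, "region_set")) regions$regions else regions
  utils::write.csv(
    as.data.frame(df)[, c("region_id", "area_mm2", "mean_depression",
                          "centroid_x", "centroid_y")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
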