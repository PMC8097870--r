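#' Nuclei detection parameters
#'
#' Condenses primary-object identification to the settings that matter for
#' Hoechst-stained nuclei: intensity threshold, size gates and declumping.
#'
#' @param threshold `"otsu"` or a fixed numeric threshold applied to the
#'   background-subtracted image.
#' @param min_area_px,max_area_px Object area gates in pixels
#'   (0 < min < max).
#' @param declump `"intensity"` (watershed on the smoothed intensity
#'   landscape, the usual choice for Hoechst nuclei), `"watershed"`
#'   (watershed on the distance transform, shape-based) or `"none"`.
#' @param exclude_border Drop objects touching the image border (default on;
#'   tiled whole-well scans handle borders at the tile level).
#' @export
nuclei_params <- function(threshold = "otsu", min_area_px = 20,
                          max_area_px = 5000,
                          declump = c("intensity", "watershed", "none"),
                          exclude_border = TRUE) {
  declump <- match.arg(declump)
  if (!(identical(threshold, "otsu") || is.numeric(threshold))) {
    abort("`threshold` must be \"otsu\" or numeric")
  }
  if (!(min_area_px > 0 && min_area_px < max_area_px)) {
    abort("need 0 < min_area_px < max_area_px")
  }
  structure(list(threshold = threshold, min_area_px = min_area_px,
                 max_area_px = max_area_px, declump = declump,
                 exclude_border = exclude_border),
            class = "nuclei_params")
}

# segment objects; returns per-object centroid/area/border-touch table
nuclei_objects <- function(image, params) {
  if (!is.matrix(image) || any(dim(image) == 0L)) abort("image must be a non-empty matrix")
  if (any(image < 0)) abort("image must be non-negative")
  bg <- median(image)
  sub <- pmax(image - bg, 0)
  mx <- max(sub)
  if (mx == 0) {
    return(tibble(x_px = numeric(0), y_px = numeric(0), area_px = numeric(0),
                  touches_top = logical(0), touches_bottom = logical(0),
                  touches_left = logical(0), touches_right = logical(0)))
  }
  thr <- if (identical(params$threshold, "otsu")) {
    # floor at a robust noise level so pure-noise images segment nothing
    max(EBImage::otsu(EBImage::Image(sub / mx), range = c(0, 1)) * mx,
        5 * mad(as.numeric(image)))
  } else {
    params$threshold
  }
  mask <- sub > thr
  labels <- switch(
    params$declump,
    none = label_components(mask, connectivity = 8),
    # shape-based: basins of the Euclidean distance transform; the small
    # tolerance matters because nuclear-scale distance maxima are only a few
    # pixels high
    watershed = as.matrix(EBImage::watershed(EBImage::distmap(mask),
                                             tolerance = 0.2)),
    # intensity-based: basins of the smoothed fluorescence landscape within
    # the mask; tolerance scaled to the threshold so read noise cannot split
    intensity = {
      sm <- as.matrix(EBImage::gblur(EBImage::Image(sub / mx), sigma = 1)) * mx
      sm[!mask] <- 0
      as.matrix(EBImage::watershed(EBImage::Image(sm), tolerance = 0.15 * thr))
    })
  n <- max(labels)
  if (n == 0L) {
    return(nuclei_objects_empty())
  }
  nr <- nrow(image); nc <- ncol(image)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  wts <- sub[idx]
  area <- tabulate(lab, n)
  wsum <- vapply(split(wts, lab), sum, numeric(1L))
  # intensity-weighted centroids (fall back to unweighted for flat objects)
  ysum <- vapply(split(wts * rr, lab), sum, numeric(1L))
  xsum <- vapply(split(wts * cc, lab), sum, numeric(1L))
  y0 <- vapply(split(rr, lab), mean, numeric(1L))
  x0 <- vapply(split(cc, lab), mean, numeric(1L))
  yc <- ifelse(wsum > 0, ysum / wsum, y0)
  xc <- ifelse(wsum > 0, xsum / wsum, x0)
  touches <- function(cond) {
    out <- logical(n)
    out[unique(lab[cond])] <- TRUE
    out
  }
  tibble(x_px = unname(xc), y_px = unname(yc), area_px = area,
         touches_top = touches(rr == 1L),
         touches_bottom = touches(rr == nr),
         touches_left = touches(cc == 1L),
         touches_right = touches(cc == nc))
}

nuclei_objects_empty <- function() {
  tibble(x_px = numeric(0), y_px = numeric(0), area_px = numeric(0),
         touches_top = logical(0), touches_bottom = logical(0),
         touches_left = logical(0), touches_right = logical(0))
}

#' Count stained nuclei in a fluorescence image
#'
#' Median background subtraction, thresholding (Otsu by default),
#' 8-connected component labelling with optional distance-transform
#' watershed declumping, then area filtering and border exclusion.
#'
#' @param image 16-bit grayscale image as a non-negative numeric matrix.
#' @param params A [nuclei_params()].
#' @return A `count_result`: list with `count`, `centroids` (tibble `x_px`,
#'   `y_px`, `area_px`; x = column, 1-based) and `rejected` counts by reason.
#' @export
count_nuclei <- function(image, params = nuclei_params()) {
  obj <- nuclei_objects(image, params)
  border <- obj$touches_top | obj$touches_bottom | obj$touches_left |
    obj$touches_right
  too_small <- obj$area_px < params$min_area_px
  too_large <- obj$area_px > params$max_area_px
  drop_border <- params$exclude_border & border & !too_small & !too_large
  keep <- !too_small & !too_large & !drop_border
  structure(list(
    count = sum(keep),
    centroids = obj[keep, c("x_px", "y_px", "area_px")],
    rejected = c(too_small = sum(too_small), too_large = sum(too_large),
                 border = sum(drop_border))),
    class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result %d nuclei (rejected: %s)>\n", x$count,
              paste(names(x$rejected), x$rejected, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Total nuclei count over a tile scan
#'
#' Sums per-tile counts over a row-major grid of overlapping tiles. Border
#' exclusion applies only on the scan's outer borders; along interior tile
#' edges each object is attributed to the tile owning its centroid, with the
#' ownership boundary in the middle of the overlap strip, so overlapping
#' objects are not double-counted.
#'
#' @param images List of tile images, row-major.
#' @param params A [nuclei_params()].
#' @param grid_dim `c(rows, cols)` of the tile grid; default a single row.
#' @param overlap_px Overlap between adjacent tiles in pixels.
#' @return List with `total` count and a per-tile tibble.
#' @export
tile_count <- function(images, params = nuclei_params(), grid_dim = NULL,
                       overlap_px = 0) {
  if (length(images) == 0L) abort("no tiles supplied")
  if (is.null(grid_dim)) grid_dim <- c(1L, length(images))
  if (prod(grid_dim) != length(images)) abort("grid_dim does not match tile count")
  margin <- overlap_px / 2
  counts <- integer(length(images))
  for (i in seq_along(images)) {
    tr <- ((i - 1L) %/% grid_dim[2L]) + 1L  # tile row
    tc <- ((i - 1L) %% grid_dim[2L]) + 1L
    obj <- nuclei_objects(images[[i]], params)
    keep <- obj$area_px >= params$min_area_px & obj$area_px <= params$max_area_px
    nr <- nrow(images[[i]]); nc <- ncol(images[[i]])
    # outer borders: exclude touching objects; interior edges: ownership margin
    if (params$exclude_border) {
      if (tr == 1L) keep <- keep & !obj$touches_top
      if (tr == grid_dim[1L]) keep <- keep & !obj$touches_bottom
      if (tc == 1L) keep <- keep & !obj$touches_left
      if (tc == grid_dim[2L]) keep <- keep & !obj$touches_right
    }
    if (tr > 1L) keep <- keep & obj$y_px > margin
    if (tr < grid_dim[1L]) keep <- keep & obj$y_px <= nr - margin
    if (tc > 1L) keep <- keep & obj$x_px > margin
    if (tc < grid_dim[2L]) keep <- keep & obj$x_px <= nc - margin
    counts[i] <- sum(keep)
  }
  list(total = sum(counts),
       tiles = tibble(tile = seq_along(images), count = counts))
}

#' Write nuclei counts / centroids as CSV
#'
#' Counts CSV contract: `tile,count`; centroids CSV: `x_px,y_px` (0-based).
#' @param result A `count_result` or the tibble from [tile_count()].
#' @param path File path.
#' @export
write_counts_csv <- function(result, path) {
  df <- if (inherits(result, "count_result")) {
    data.frame(tile = 1L, count = result$count)
  } else {
    as.data.frame(result$tiles %||% result)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
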