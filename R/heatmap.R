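#' Render an analyte map as a PNG heat map
#'
#' Fixed value-to-colour mapping over `range`, with a vertical colour bar on
#' the right. Invalid pixels render grey. Output bytes are deterministic for
#' fixed input and settings.
#'
#' @param map An [analyte_map()] or [ratio_map()].
#' @param path Output PNG path.
#' @param range Value range pinned to the colormap endpoints; defaults to the
#'   finite data range.
#' @param colormap Palette name passed to [grDevices::hcl.colors()].
#' @param n_colors Number of palette levels.
#' @param colorbar Draw the colour bar strip.
#' @return Invisibly, the RGB array written.
#' @export
render_heatmap <- function(map, path, range = NULL, colormap = "viridis",
                           n_colors = 256L, colorbar = TRUE) {
  rgb <- map_to_rgb(map$values, range, colormap, n_colors)
  if (colorbar) {
    h <- dim(rgb)[1L]
    bar_cols <- t(col2rgb(hcl.colors(h, colormap, rev = TRUE))) / 255
    bar <- array(0, c(h, 14L, 3L))
    bar[, 1:4, ] <- 1  # white gap
    for (k in 1:3) bar[, 5:14, k] <- matrix(bar_cols[, k], h, 10L)
    rgb <- abind_cols(rgb, bar)
  }
  png::writePNG(rgb, path)
  invisible(rgb)
}

# value matrix -> H x W x 3 array in [0,1]
map_to_rgb <- function(values, range = NULL, colormap = "viridis",
                       n_colors = 256L) {
  fin <- is.finite(values)
  if (is.null(range)) {
    range <- if (any(fin)) base::range(values[fin]) else c(0, 1)
  }
  pal <- t(col2rgb(hcl.colors(n_colors, colormap))) / 255
  span <- if (diff(range) > 0) diff(range) else 1
  idx <- pmin(pmax((values - range[1L]) / span, 0), 1)
  idx <- matrix(as.integer(round(idx * (n_colors - 1L))) + 1L,
                nrow(values), ncol(values))
  rgb <- array(0.5, c(nrow(values), ncol(values), 3L))  # grey for invalid
  for (k in 1:3) {
    plane <- matrix(0.5, nrow(values), ncol(values))
    plane[fin] <- pal[idx[fin], k]
    rgb[, , k] <- plane
  }
  rgb
}

abind_cols <- function(a, b) {
  stopifnot(dim(a)[1L] == dim(b)[1L], dim(a)[3L] == dim(b)[3L])
  out <- array(0, c(dim(a)[1L], dim(a)[2L] + dim(b)[2L], 3L))
  out[, seq_len(dim(a)[2L]), ] <- a
  out[, dim(a)[2L] + seq_len(dim(b)[2L]), ] <- b
  out
}

#' Overlay boundary outlines of masks on a heat map
#'
#' Draws the morphological gradient (mask minus its erosion) of each supplied
#' boolean mask in a contrasting colour over the rendered map, as used to
#' mark cell-layer borders on pO2/pH heat maps.
#'
#' @param map An [analyte_map()] or [ratio_map()].
#' @param masks A logical matrix or list of logical matrices matching the
#'   map's dimensions.
#' @param colours Colour per mask (any R colour spec).
#' @param path Optional PNG output path.
#' @inheritParams render_heatmap
#' @return Invisibly, the composite RGB array.
#' @export
overlay_outline <- function(map, masks, colours = "white", path = NULL,
                            range = NULL, colormap = "viridis") {
  if (is.matrix(masks)) masks <- list(masks)
  colours <- rep_len(colours, length(masks))
  rgb <- map_to_rgb(map$values, range, colormap)
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    if (!is.matrix(m) || !all(dim(m) == dim(map$values))) {
      abort("outline mask shape does not match the map")
    }
    outline <- mask_outline(m & TRUE)
    col <- col2rgb(colours[i])[, 1L] / 255
    for (k in 1:3) {
      plane <- rgb[, , k]
      plane[outline] <- col[k]
      rgb[, , k] <- plane
    }
  }
  if (!is.null(path)) png::writePNG(rgb, path)
  invisible(rgb)
}

# boundary pixels: in the mask but with a 4-neighbour outside it
mask_outline <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  eroded <- mask & pad(mask, 1L, 0L) & pad(mask, -1L, 0L) &
    pad(mask, 0L, 1L) & pad(mask, 0L, -1L)
  mask & !eroded
}
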