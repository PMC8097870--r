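#' Construct a two-channel frame stack
#'
#' The raw input of the pipeline: a time-ordered stack of two-channel sensor
#' images (sensitive and reference luminophore channels) in camera units.
#'
#' @param frames Numeric array `T x H x W x 2` of non-negative intensities.
#' @param timestamps_s Strictly increasing acquisition times (length T).
#' @param channel_roles Named integer vector mapping `sensitive` and
#'   `reference` to channel indices.
#' @param pixel_size_mm Pixel edge length in mm.
#' @param batch_id Sensor-foil batch identifier (matched against the
#'   calibration at conversion time).
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, timestamps_s,
                        channel_roles = c(sensitive = 1L, reference = 2L),
                        pixel_size_mm = 1, batch_id = "") {
  if (length(dim(frames)) != 4L || dim(frames)[4L] != 2L) {
    abort("`frames` must be a T x H x W x 2 array")
  }
  if (dim(frames)[1L] != length(timestamps_s)) {
    abort("`timestamps_s` length must equal the number of frames")
  }
  if (length(timestamps_s) > 1L && any(diff(timestamps_s) <= 0)) {
    abort("`timestamps_s` must be strictly increasing")
  }
  if (any(frames < 0)) abort("intensities must be >= 0")
  if (!all(c("sensitive", "reference") %in% names(channel_roles))) {
    abort("`channel_roles` must name `sensitive` and `reference`")
  }
  structure(list(frames = frames, timestamps_s = as.numeric(timestamps_s),
                 channel_roles = channel_roles,
                 pixel_size_mm = pixel_size_mm, batch_id = batch_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack %d frames, %dx%d px, 2 channels, t = [%g, %g] s>\n",
              d[1L], d[2L], d[3L], min(x$timestamps_s), max(x$timestamps_s)))
  invisible(x)
}

#' Write / read a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are written as per-timepoint channel pairs (channel 1 then channel 2
#' for each frame), 16-bit, with the intensity scale and all metadata
#' (timestamps, channel roles, pixel size, batch) recorded in
#' `<path>.json`.
#'
#' @param stack A [frame_stack()].
#' @param path Output `.tif` path; the sidecar is written next to it.
#' @export
write_frame_stack <- function(stack, path) {
  d <- dim(stack$frames)
  scale <- max(stack$frames, 1)
  pages <- vector("list", d[1L] * 2L)
  for (t in seq_len(d[1L])) {
    for (ch in 1:2) {
      pages[[(t - 1L) * 2L + ch]] <- pmin(stack$frames[t, , , ch] / scale, 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(layout = "page_pairs", n_frames = d[1L],
               height = d[2L], width = d[3L],
               intensity_scale = scale,
               timestamps_s = stack$timestamps_s,
               channel_roles = as.list(stack$channel_roles),
               pixel_size_mm = stack$pixel_size_mm,
               batch_id = stack$batch_id)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, c(meta$n_frames, meta$height, meta$width, 2L))
  for (t in seq_len(meta$n_frames)) {
    for (ch in 1:2) {
      frames[t, , , ch] <- pages[[(t - 1L) * 2L + ch]] * meta$intensity_scale
    }
  }
  frame_stack(frames, meta$timestamps_s,
              channel_roles = unlist(meta$channel_roles),
              pixel_size_mm = meta$pixel_size_mm, batch_id = meta$batch_id)
}
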