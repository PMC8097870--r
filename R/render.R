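#' Render simulated analyte maps into a raw sensor frame stack
#'
#' Forward optical model of the ratiometric foil readout. Per pixel,
#' the reference channel is `exposure_scale * base_intensity`, the sensitive
#' channel is `ratio_model(F(x)) * M(x)` times the same baseline, where
#' `M(x)` is the acquisition's illumination-mismatch field. Optional camera
#' noise (shot-like, SD proportional to sqrt(intensity), plus additive read
#' noise) is applied independently per channel; intensities are floored at 0.
#' Rendering is a pure function of `(maps, cal, acq)`: the same seed gives a
#' bit-identical stack.
#'
#' @param maps List of [analyte_map()]s (output of [simulate_fields()]).
#' @param cal Fitted calibration whose forward model maps analyte to ratio;
#'   all map values must lie in the calibration's invertible range.
#' @param acq An [acquisition_spec()]; supplies mismatch, noise and seed.
#' @param base_intensity Baseline camera intensity of the reference channel.
#' @param batch_id Batch identifier stamped on the stack.
#' @return A [frame_stack()].
#' @export
render_frames <- function(maps, cal, acq, base_intensity = 1000,
                          batch_id = "") {
  stopifnot(length(maps) >= 1L, inherits(acq, "acquisition_spec"))
  dims <- dim(maps[[1L]]$values)
  analyte <- maps[[1L]]$analyte
  if (analyte == "O2") {
    if (any(vapply(maps, function(m) any(m$values < 0), logical(1L)))) {
      abort("O2 maps must be >= 0 (outside invertible range)")
    }
  } else {
    lo <- min(cal$ph_range); hi <- max(cal$ph_range)
    rng <- range(vapply(maps, function(m) range(m$values), numeric(2L)))
    if (rng[1L] < lo - 1 || rng[2L] > hi + 1) {
      abort("pH maps extend far outside the calibrated range")
    }
  }
  m_field <- acq$illumination_mismatch
  if (is.null(m_field)) m_field <- 1
  if (is.matrix(m_field) && !all(dim(m_field) == dims)) {
    abort("illumination_mismatch dimensions do not match the maps")
  }
  g0 <- acq$exposure_scale * base_intensity
  frames <- array(0, c(length(maps), dims[1L], dims[2L], 2L))
  with_seed(acq$seed, {
    for (t in seq_along(maps)) {
      sens <- predict_ratio(cal, maps[[t]]$values) * m_field * g0
      ref <- matrix(g0, dims[1L], dims[2L])
      frames[t, , , 1L] <- add_camera_noise(sens, acq)
      frames[t, , , 2L] <- add_camera_noise(ref, acq)
    }
  })
  frame_stack(frames,
              timestamps_s = vapply(maps, `[[`, numeric(1L), "timestamp_s"),
              channel_roles = c(sensitive = 1L, reference = 2L),
              pixel_size_mm = maps[[1L]]$pixel_size_mm,
              batch_id = batch_id)
}

# CMOS-style noise: I + sqrt(I) N(0,1) [shot] + read_noise_sd N(0,1) [read]
add_camera_noise <- function(intensity, acq) {
  out <- intensity
  n <- length(intensity)
  if (acq$shot_noise) {
    out <- out + sqrt(pmax(intensity, 0)) * stats::rnorm(n)
  }
  if (acq$read_noise_sd > 0) {
    out <- out + acq$read_noise_sd * stats::rnorm(n)
  }
  pmax(out, 0)
}

#' Render a Hoechst-like nuclei image with ground truth
#'
#' Draws each patch's nuclei as Gaussian spots (sigma = the cell type's
#' `nucleus_radius_px`) on a constant background with read noise, at the
#' nuclei-camera pixel scale (a microscope tile, finer than the sensor-foil
#' grid). The expected nucleus count per patch is `density x patch area`;
#' positions are sampled uniformly within the patch, optionally with a
#' minimum-separation rejection rule.
#'
#' @param spec A [scene_spec()].
#' @param acq An [acquisition_spec()] (supplies seed and read noise).
#' @param pixel_size_mm Nuclei-image pixel size in mm (default 5 um).
#' @param amplitude Peak intensity of one nucleus above background.
#' @param background Constant background level (camera units).
#' @param min_separation_px Optional minimum centre-to-centre distance;
#'   sampling errors out after `max_tries` rejections per nucleus.
#' @param max_tries Bounded retries per nucleus for the rejection rule.
#' @return List with `image` (16-bit integer matrix), `centroids` (tibble
#'   `x_px`, `y_px`, `cell_type`; x = column, y = row, 1-based) and
#'   `pixel_size_mm`.
#' @export
render_nuclei_image <- function(spec, acq, pixel_size_mm = 0.005,
                                amplitude = 10000, background = 500,
                                min_separation_px = 0, max_tries = 500L) {
  stopifnot(inherits(spec, "scene_spec"), inherits(acq, "acquisition_spec"))
  scale <- spec$pixel_size_mm / pixel_size_mm  # nuclei px per sim px
  nr <- max(1L, round(spec$grid_shape[1L] * scale))
  nc <- max(1L, round(spec$grid_shape[2L] * scale))
  img <- matrix(0, nr, nc)
  masks <- patch_masks(spec)
  cents <- list()
  px_area_cm2 <- (spec$pixel_size_mm / 10)^2
  with_seed(acq$seed, {
    placed_x <- numeric(0); placed_y <- numeric(0)
    for (i in seq_along(masks)) {
      ct_name <- spec$patches[[i]]$cell_type
      ct <- spec$cell_types[[ct_name]]
      n <- round(ct$density * sum(masks[[i]]) * px_area_cm2)
      if (n == 0L) next
      cand <- which(masks[[i]])
      rr <- ((cand - 1L) %% spec$grid_shape[1L]) + 1L
      cc <- ((cand - 1L) %/% spec$grid_shape[1L]) + 1L
      xs <- numeric(n); ys <- numeric(n)
      for (j in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          pick <- sample.int(length(cand), 1L)
          y <- (rr[pick] - stats::runif(1)) * scale
          x <- (cc[pick] - stats::runif(1)) * scale
          if (min_separation_px <= 0 || length(placed_x) == 0L ||
              min((placed_x - x)^2 + (placed_y - y)^2) >= min_separation_px^2) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          abort(sprintf(
            "could not place nucleus %d of patch %d with min separation %g px",
            j, i, min_separation_px))
        }
        xs[j] <- x; ys[j] <- y
        placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      }
      cents[[i]] <- tibble(x_px = xs, y_px = ys, cell_type = ct_name)
    }
    # accumulate spots in place (one pass; windows of +-4 sigma)
    for (i in seq_along(cents)) {
      if (is.null(cents[[i]])) next
      sigma <- spec$cell_types[[spec$patches[[i]]$cell_type]]$nucleus_radius_px
      h <- ceiling(4 * sigma)
      for (j in seq_len(nrow(cents[[i]]))) {
        y <- cents[[i]]$y_px[j]; x <- cents[[i]]$x_px[j]
        r0 <- max(1L, floor(y - h)); r1 <- min(nr, ceiling(y + h))
        c0 <- max(1L, floor(x - h)); c1 <- min(nc, ceiling(x + h))
        if (r0 > r1 || c0 > c1) next
        rs <- r0:r1; csq <- c0:c1
        img[rs, csq] <- img[rs, csq] +
          amplitude * outer(exp(-(rs - y)^2 / (2 * sigma^2)),
                            exp(-(csq - x)^2 / (2 * sigma^2)))
      }
    }
    img <- img + background
    if (acq$read_noise_sd > 0) {
      img <- img + acq$read_noise_sd * stats::rnorm(length(img))
    }
  })
  img <- matrix(as.integer(pmin(pmax(round(img), 0), 65535L)), nr, nc)
  centroids <- if (length(cents)) dplyr::bind_rows(cents) else
    tibble(x_px = numeric(0), y_px = numeric(0), cell_type = character(0))
  list(image = img, centroids = centroids, pixel_size_mm = pixel_size_mm)
}

#' Write / read a 16-bit grayscale nuclei image as TIFF
#'
#' @param image Integer matrix (0..65535).
#' @param path File path.
#' @export
write_nuclei_image <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_nuclei_image
#' @export
read_nuclei_image <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write ground-truth centroids as CSV
#'
#' CSV contract: `x_px,y_px` (0-based pixel coordinates, x = column).
#' @param centroids Tibble with `x_px`, `y_px` (1-based, as returned by
#'   [render_nuclei_image()]).
#' @param path File path.
#' @export
write_centroids <- function(centroids, path) {
  out <- data.frame(x_px = centroids$x_px - 1, y_px = centroids$y_px - 1)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
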