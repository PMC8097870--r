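#' Define a cell type for the micro-respirator simulator
#'
#' A cell type bundles the areal seeding density with the per-cell metabolic
#' coefficients used by the simulator. `k_o2` and `k_ph` are effective sink
#' coefficients: the local depletion rate of the analyte field at the
#' reference chamber height is `k * density` (in % air saturation per second
#' for oxygen, pH units per second for pH).
#'
#' @param density Areal cell density in cells/cm^2 (>= 0).
#' @param k_o2 Oxygen sink coefficient, (% air-sat/s) per (cells/cm^2) at the
#'   reference chamber height.
#' @param k_ph Acidification coefficient, (pH/s) per (cells/cm^2); buffering
#'   is folded into this effective value.
#' @param nucleus_radius_px Gaussian radius (sigma, in nuclei-image pixels;
#'   default 1.5 px at the 5-um default nuclei pixel scale)
#'   used when rendering Hoechst-like nuclei images.
#' @return A `cell_type` list.
#' @export
cell_type <- function(density, k_o2 = 0, k_ph = 0, nucleus_radius_px = 1.5) {
  assert_scalar_num(density, "density", 0)
  assert_scalar_num(k_o2, "k_o2", 0)
  assert_scalar_num(k_ph, "k_ph", 0)
  assert_scalar_num(nucleus_radius_px, "nucleus_radius_px", 0, strict = TRUE)
  structure(list(density = density, k_o2 = k_o2, k_ph = k_ph,
                 nucleus_radius_px = nucleus_radius_px),
            class = "cell_type")
}

#' Rectangular patch helper
#'
#' @param rows,cols Integer ranges (inclusive, 1-based) of the patch within
#'   the simulation grid.
#' @param cell_type Name of a cell type defined in the scene.
#' @return A patch description usable in [scene_spec()].
#' @export
rect_patch <- function(rows, cols, cell_type) {
  list(rows = range(as.integer(rows)), cols = range(as.integer(cols)),
       cell_type = cell_type)
}

#' Mask patch helper
#'
#' @param mask Logical matrix with the simulation grid's dimensions.
#' @param cell_type Name of a cell type defined in the scene.
#' @export
mask_patch <- function(mask, cell_type) {
  list(mask = mask, cell_type = cell_type)
}

#' Specify a synthetic micro-respirator scene
#'
#' The scene is the simulator's ground truth: a pixel grid carrying patches of
#' cells (colonies, inserts, mixed layouts), the chamber geometry of the
#' thin medium layer trapped under the sensor foil, and the initial analyte
#' levels. Chamber height enters the physics only through the factor
#' `reference_height_mm / height_mm`: a thinner trapped layer makes the
#' apparent depletion proportionally faster.
#'
#' @param grid_shape Integer `(rows, cols)` of the simulation grid.
#' @param pixel_size_mm Edge length of one simulation pixel in mm.
#' @param cell_types Named list of [cell_type()] objects.
#' @param patches List of [rect_patch()] / [mask_patch()] entries. Patches
#'   must not overlap.
#' @param chamber List with `height_mm`, `reference_height_mm` and
#'   `D_eff_mm2_per_s` (effective lateral diffusion coefficient, >= 0).
#' @param initial_o2_pct Initial oxygen level, % air saturation.
#' @param initial_ph Initial pH.
#' @return A validated `scene_spec` object.
#' @examples
#' sc <- scene_spec(
#'   grid_shape = c(40, 40), pixel_size_mm = 0.1,
#'   cell_types = list(tumour = cell_type(66000, k_o2 = 7.6e-7)),
#'   patches = list(rect_patch(11:25, 11:25, "tumour"))
#' )
#' range(build_density_map(sc))
#' @export
scene_spec <- function(grid_shape, pixel_size_mm,
                       cell_types = list(), patches = list(),
                       chamber = list(height_mm = 0.1,
                                      reference_height_mm = 0.1,
                                      D_eff_mm2_per_s = 0),
                       initial_o2_pct = 100, initial_ph = 7.4) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape < 1L)) {
    abort("`grid_shape` must be two positive integers (rows, cols)")
  }
  assert_scalar_num(pixel_size_mm, "pixel_size_mm", 0, strict = TRUE)
  if (length(cell_types) && is.null(names(cell_types))) {
    abort("`cell_types` must be a named list")
  }
  for (ct in cell_types) {
    if (!inherits(ct, "cell_type")) abort("all `cell_types` must be created with cell_type()")
  }
  chamber <- utils::modifyList(
    list(height_mm = 0.1, reference_height_mm = 0.1, D_eff_mm2_per_s = 0),
    chamber)
  assert_scalar_num(chamber$height_mm, "chamber$height_mm", 0, strict = TRUE)
  assert_scalar_num(chamber$reference_height_mm, "chamber$reference_height_mm",
                    0, strict = TRUE)
  assert_scalar_num(chamber$D_eff_mm2_per_s, "chamber$D_eff_mm2_per_s", 0)

  spec <- structure(
    list(grid_shape = grid_shape, pixel_size_mm = pixel_size_mm,
         cell_types = cell_types, patches = patches, chamber = chamber,
         initial_o2_pct = initial_o2_pct, initial_ph = initial_ph),
    class = "scene_spec")
  # validate patches (in-bounds, known cell types, no overlap)
  patch_masks(spec)
  spec
}

# materialise every patch as a logical matrix; errors on overlap / bad refs
patch_masks <- function(spec) {
  nr <- spec$grid_shape[1L]; nc <- spec$grid_shape[2L]
  seen <- matrix(FALSE, nr, nc)
  masks <- vector("list", length(spec$patches))
  for (i in seq_along(spec$patches)) {
    p <- spec$patches[[i]]
    if (!p$cell_type %in% names(spec$cell_types)) {
      abort(sprintf("patch %d references unknown cell type '%s'", i, p$cell_type))
    }
    if (!is.null(p$mask)) {
      m <- p$mask
      if (!is.matrix(m) || !all(dim(m) == c(nr, nc))) {
        abort(sprintf("patch %d mask does not match grid_shape", i))
      }
      m <- m & TRUE
    } else {
      if (p$rows[1L] < 1L || p$rows[2L] > nr || p$cols[1L] < 1L || p$cols[2L] > nc) {
        abort(sprintf("patch %d lies outside the grid", i))
      }
      m <- matrix(FALSE, nr, nc)
      m[p$rows[1L]:p$rows[2L], p$cols[1L]:p$cols[2L]] <- TRUE
    }
    if (any(seen & m)) abort(sprintf("patch %d overlaps an earlier patch", i))
    seen <- seen | m
    masks[[i]] <- m
  }
  masks
}

#' Ground-truth areal cell density map of a scene
#'
#' @param spec A [scene_spec()].
#' @return Numeric matrix (rows x cols) of cell densities in cells/cm^2:
#'   the patch's cell-type density inside each patch, 0 elsewhere.
#' @export
build_density_map <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  dens <- matrix(0, spec$grid_shape[1L], spec$grid_shape[2L])
  masks <- patch_masks(spec)
  for (i in seq_along(masks)) {
    ct <- spec$cell_types[[spec$patches[[i]]$cell_type]]
    dens[masks[[i]]] <- ct$density
  }
  dens
}

# per-pixel sink-rate map (analyte units per second at actual chamber height)
sink_rate_map <- function(spec, analyte = c("O2", "pH")) {
  analyte <- match.arg(analyte)
  key <- if (analyte == "O2") "k_o2" else "k_ph"
  rate <- matrix(0, spec$grid_shape[1L], spec$grid_shape[2L])
  masks <- patch_masks(spec)
  hf <- spec$chamber$reference_height_mm / spec$chamber$height_mm
  for (i in seq_along(masks)) {
    ct <- spec$cell_types[[spec$patches[[i]]$cell_type]]
    rate[masks[[i]]] <- ct[[key]] * ct$density * hf
  }
  rate
}

#' Specify an acquisition protocol
#'
#' Mirrors the instrument settings of a measurement run: frame interval and
#' total duration, an overall exposure scaling, a per-pixel illumination
#' mismatch field (the spatial bias a one-point adjustment later corrects),
#' and the camera noise model (multiplicative shot-like noise with SD
#' proportional to the square root of intensity, plus additive Gaussian read
#' noise).
#'
#' @param interval_s Frame interval in seconds (> 0). Short-term protocols in
#'   this field typically use 10-s (pH) or 20-s (O2) intervals.
#' @param duration_s Total duration in seconds (>= interval_s).
#' @param exposure_scale Overall intensity scaling (> 0).
#' @param illumination_mismatch Either `NULL` (no mismatch), a positive
#'   scalar, or a positive matrix matching the scene grid; acts as a
#'   multiplicative bias on the sensitive channel.
#' @param read_noise_sd Additive Gaussian read noise SD in camera units (>= 0).
#' @param shot_noise Logical; add sqrt(intensity)-scaled Gaussian noise.
#' @param seed Integer seed; all stochastic rendering is a pure function of
#'   (scene, acquisition, seed).
#' @return An `acquisition_spec` object.
#' @export
acquisition_spec <- function(interval_s = 20, duration_s = 600,
                             exposure_scale = 1,
                             illumination_mismatch = NULL,
                             read_noise_sd = 0, shot_noise = FALSE,
                             seed = 1L) {
  assert_scalar_num(interval_s, "interval_s", 0, strict = TRUE)
  assert_scalar_num(duration_s, "duration_s", 0, strict = TRUE)
  if (duration_s < interval_s) abort("`duration_s` must be >= `interval_s`")
  assert_scalar_num(exposure_scale, "exposure_scale", 0, strict = TRUE)
  assert_scalar_num(read_noise_sd, "read_noise_sd", 0)
  if (!is.null(illumination_mismatch)) {
    if (any(!is.finite(illumination_mismatch)) || any(illumination_mismatch <= 0)) {
      abort("`illumination_mismatch` must be strictly positive")
    }
  }
  structure(list(interval_s = interval_s, duration_s = duration_s,
                 exposure_scale = exposure_scale,
                 illumination_mismatch = illumination_mismatch,
                 read_noise_sd = read_noise_sd,
                 shot_noise = isTRUE(shot_noise),
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

acq_timestamps <- function(acq) {
  seq(0, acq$duration_s, by = acq$interval_s)
}
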