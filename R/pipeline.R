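# run configuration: YAML schema, validation, and the orchestrated pipeline

config_schema <- function() {
  list(
    seed = NULL,
    analyte = NULL,
    scene = list(
      grid_shape = NULL, pixel_size_mm = NULL,
      initial_o2_pct = NULL, initial_ph = NULL,
      chamber = list(height_mm = NULL, reference_height_mm = NULL,
                     D_eff_mm2_per_s = NULL),
      cell_types = "named_any",   # free names; values validated by cell_type()
      patches = "list_of_patch"),
    acquisition = list(interval_s = NULL, duration_s = NULL,
                       exposure_scale = NULL, read_noise_sd = NULL,
                       shot_noise = NULL),
    calibration = list(batch_id = NULL,
                       o2 = list(r0 = NULL, ksv = NULL, table = NULL),
                       ph = list(r_acid = NULL, r_base = NULL, pka = NULL,
                                 s = NULL, table = NULL)),
    smoothing_factor = NULL,
    opa = list(enabled = NULL, expected_value = NULL),
    rois = "list_of_roi",
    kinetics = list(r2_threshold = NULL, min_fraction = NULL,
                    min_points = NULL),
    nuclei = list(enabled = NULL, pixel_size_mm = NULL, amplitude = NULL,
                  background = NULL,
                  params = list(threshold = NULL, min_area_px = NULL,
                                max_area_px = NULL, declump = NULL,
                                exclude_border = NULL)),
    spatial = list(enabled = NULL, k = NULL, min_area_mm2 = NULL),
    stats = list(enabled = NULL),
    heatmap = list(colormap = NULL))
}

validate_config_keys <- function(cfg, schema, path = "") {
  for (key in names(cfg)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(schema)) {
      abort(sprintf("unknown configuration key: `%s`", full))
    }
    sub <- schema[[key]]
    if (is.list(sub) && is.list(cfg[[key]])) {
      validate_config_keys(cfg[[key]], sub, full)
    } else if (identical(sub, "list_of_patch")) {
      for (i in seq_along(cfg[[key]])) {
        validate_config_keys(cfg[[key]][[i]],
                             list(rows = NULL, cols = NULL, cell_type = NULL),
                             sprintf("%s[%d]", full, i))
      }
    } else if (identical(sub, "list_of_roi")) {
      for (i in seq_along(cfg[[key]])) {
        validate_config_keys(cfg[[key]][[i]],
                             list(label = NULL, patch = NULL, group = NULL),
                             sprintf("%s[%d]", full, i))
      }
    }
  }
  invisible(cfg)
}

#' Read and validate a pipeline run configuration
#'
#' YAML configuration with a fixed schema; unknown keys are rejected by
#' name. See `inst/extdata/demo_config.yaml` for a complete example.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config_keys(cfg, config_schema())
  required <- c("seed", "analyte", "scene", "acquisition", "calibration")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(paste("missing configuration keys:", paste(missing, collapse = ", ")))
  }
  if (!cfg$analyte %in% c("O2", "pH")) abort("`analyte` must be O2 or pH")
  structure(cfg, class = "run_config")
}

config_scene <- function(cfg) {
  sc <- cfg$scene
  cts <- lapply(sc$cell_types, function(ct) {
    cell_type(density = ct$density, k_o2 = ct$k_o2 %||% 0,
              k_ph = ct$k_ph %||% 0,
              nucleus_radius_px = ct$nucleus_radius_px %||% 1.5)
  })
  patches <- lapply(sc$patches, function(p) {
    rect_patch(p$rows[1L]:p$rows[2L], p$cols[1L]:p$cols[2L], p$cell_type)
  })
  scene_spec(grid_shape = unlist(sc$grid_shape),
             pixel_size_mm = sc$pixel_size_mm,
             cell_types = cts, patches = patches,
             chamber = sc$chamber %||% list(),
             initial_o2_pct = sc$initial_o2_pct %||% 100,
             initial_ph = sc$initial_ph %||% 7.4)
}

config_calibration <- function(cfg) {
  batch <- cfg$calibration$batch_id %||% ""
  if (cfg$analyte == "O2") {
    o2 <- cfg$calibration$o2
    if (!is.null(o2$table)) return(fit_o2_calibration(read_calibration_table(o2$table), batch))
    fit_o2_calibration(
      calibration_table(c(0, 100), c(o2$r0, o2$r0 / (1 + 100 * o2$ksv))),
      batch_id = batch)
  } else {
    ph <- cfg$calibration$ph
    if (!is.null(ph$table)) return(fit_ph_calibration(read_calibration_table(ph$table), batch))
    truth <- structure(list(r_acid = ph$r_acid, r_base = ph$r_base,
                            pka = ph$pka, s = ph$s, ph_range = c(5, 8.5)),
                       class = "ph_calibration")
    pts <- seq(5, 8.5, length.out = 6)
    fit_ph_calibration(calibration_table(pts, predict_ratio(truth, pts)),
                       batch_id = batch)
  }
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in fixed order — simulate, render, ratio, OPA,
#' smooth, calibrate, ROI extraction, kinetics, nuclei counting, spatial
#' detection, group statistics — writing every product (TIFF stacks with
#' JSON sidecars, CSV tables, PNG heat maps) into `out_dir` together with a
#' `manifest.json` listing MD5 checksums of all products and of the
#' configuration. Identical configuration and seed give identical checksums.
#'
#' @param config A `run_config` from [read_run_config()] (or a path to one).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  products <- character(0)
  pth <- function(f) file.path(out_dir, f)
  add <- function(f) products <<- c(products, f)
  log_stage <- function(stage, t0, ...) {
    message(sprintf("[%s] %.2fs %s", stage,
                    as.numeric(Sys.time()) - t0, paste(..., collapse = " ")))
  }

  t0 <- as.numeric(Sys.time())
  spec <- config_scene(config)
  cal <- config_calibration(config)
  write_calibration(cal, pth("calibration.json")); add("calibration.json")

  acq <- acquisition_spec(
    interval_s = config$acquisition$interval_s,
    duration_s = config$acquisition$duration_s,
    exposure_scale = config$acquisition$exposure_scale %||% 1,
    read_noise_sd = config$acquisition$read_noise_sd %||% 0,
    shot_noise = config$acquisition$shot_noise %||% FALSE,
    seed = derive_seed(config$seed, 1L))

  # simulate + render
  maps_true <- simulate_fields(spec, acq, config$analyte)
  stack <- render_frames(maps_true, cal, acq,
                         batch_id = config$calibration$batch_id %||% "")
  write_frame_stack(stack, pth("stack.tif"))
  add("stack.tif"); add("stack.tif.json")
  log_stage("simulate", t0, sprintf("%d frames", length(maps_true)))

  # ratio -> OPA -> smooth -> calibrate
  sm <- config$smoothing_factor %||% 0
  opa_field <- NULL
  if (isTRUE(config$opa$enabled)) {
    # uniform reference frame: first frame is near-initial and serves as the
    # one-point image; expected ratio from the calibration at the initial value
    init <- if (config$analyte == "O2") spec$initial_o2_pct else spec$initial_ph
    expected <- config$opa$expected_value %||% predict_ratio(cal, init)
    opa_field <- fit_illumination(compute_ratio(stack, 1L), expected)
  }
  analyte_maps <- lapply(seq_along(stack$timestamps_s), function(t) {
    rm_ <- compute_ratio(stack, t)
    if (!is.null(opa_field)) rm_ <- apply_opa(rm_, opa_field)
    rm_ <- smooth_map(rm_, sm)
    apply_calibration(rm_, cal, batch_id = stack$batch_id)
  })
  cmap <- config$heatmap$colormap %||% "viridis"
  vrange <- range(vapply(analyte_maps,
                         function(m) range(m$values[is.finite(m$values)]),
                         numeric(2L)))
  render_heatmap(analyte_maps[[1L]], pth("heatmap_first.png"),
                 range = vrange, colormap = cmap)
  render_heatmap(analyte_maps[[length(analyte_maps)]], pth("heatmap_last.png"),
                 range = vrange, colormap = cmap)
  add("heatmap_first.png"); add("heatmap_last.png")
  log_stage("convert", t0)

  # nuclei (cell counts for normalisation)
  masks <- patch_masks(spec)
  counts_px <- NULL
  if (isTRUE(config$nuclei$enabled)) {
    nacq <- acq
    nacq$seed <- derive_seed(config$seed, 2L)
    npx <- config$nuclei$pixel_size_mm %||% 0.01
    nuc <- render_nuclei_image(spec, nacq, pixel_size_mm = npx,
                               amplitude = config$nuclei$amplitude %||% 10000,
                               background = config$nuclei$background %||% 500)
    write_nuclei_image(nuc$image, pth("nuclei.tif")); add("nuclei.tif")
    write_centroids(nuc$centroids, pth("nuclei_truth.csv")); add("nuclei_truth.csv")
    np <- config$nuclei$params %||% list()
    params <- nuclei_params(threshold = np$threshold %||% "otsu",
                            min_area_px = np$min_area_px %||% 5,
                            max_area_px = np$max_area_px %||% 5000,
                            declump = np$declump %||% "watershed",
                            exclude_border = np$exclude_border %||% FALSE)
    cres <- count_nuclei(nuc$image, params)
    write_counts_csv(cres, pth("nuclei_counts.csv")); add("nuclei_counts.csv")
    counts_px <- list(centroids = cres$centroids,
                      scale = spec$pixel_size_mm / npx)
    log_stage("nuclei", t0, sprintf("%d counted", cres$count))
  }

  # ROI time series + rates
  rates <- NULL
  if (length(config$rois)) {
    px_area_cm2 <- (spec$pixel_size_mm / 10)^2
    kin <- config$kinetics %||% list()
    rate_rows <- list()
    for (i in seq_along(config$rois)) {
      roi_cfg <- config$rois[[i]]
      mask <- masks[[roi_cfg$patch]]
      ts <- extract_roi_timeseries(analyte_maps, mask)
      write_timeseries_csv(ts, pth(sprintf("roi_%s_timeseries.csv", roi_cfg$label)))
      add(sprintf("roi_%s_timeseries.csv", roi_cfg$label))
      win <- find_linear_range(ts,
                               r2_threshold = kin$r2_threshold %||% 0.99,
                               min_fraction = kin$min_fraction %||% 0.3,
                               min_points = kin$min_points %||% 10L)
      fit <- fit_slope(ts, win)
      cells <- if (!is.null(counts_px)) {
        # attribute counted nuclei to the ROI by position
        xs <- counts_px$centroids$x_px / counts_px$scale
        ys <- counts_px$centroids$y_px / counts_px$scale
        inside <- mask[cbind(pmin(pmax(ceiling(ys), 1L), nrow(mask)),
                             pmin(pmax(ceiling(xs), 1L), ncol(mask)))]
        max(sum(inside), 1L)
      } else {
        ct <- spec$cell_types[[spec$patches[[roi_cfg$patch]]$cell_type]]
        max(round(ct$density * sum(mask) * px_area_cm2), 1L)
      }
      rr <- normalize_rate(fit, cells,
                           kind = if (config$analyte == "O2") "OCR" else "ECAR")
      rr$roi <- roi_cfg$label
      rr$group <- roi_cfg$group %||% roi_cfg$label
      rate_rows[[i]] <- rr
    }
    rates <- dplyr::bind_rows(rate_rows)
    write_rates_csv(rates, pth("rates.csv")); add("rates.csv")
    log_stage("rates", t0, sprintf("%d ROIs", nrow(rates)))
  }

  # spatial detection on the final map
  if (!isFALSE(config$spatial$enabled)) {
    sp <- config$spatial %||% list()
    params <- detection_params(k = sp$k %||% 5,
                               min_area_mm2 = sp$min_area_mm2 %||% 0.1)
    rs <- detect_active_regions(analyte_maps[[length(analyte_maps)]], params)
    write_regions_csv(rs, pth("regions.csv")); add("regions.csv")
    truth <- Reduce(`|`, masks, matrix(FALSE, spec$grid_shape[1L], spec$grid_shape[2L]))
    overlay_outline(analyte_maps[[length(analyte_maps)]], truth,
                    colours = "white", path = pth("overlay.png"),
                    range = vrange, colormap = cmap)
    add("overlay.png")
    log_stage("spatial", t0, sprintf("%d regions", nrow(rs$regions)))
  }

  # group statistics on normalised rates
  if (isTRUE(config$stats$enabled) && !is.null(rates)) {
    gd <- tibble(group = rates$group, value = rates$normalized_rate)
    if (length(unique(gd$group)) >= 2L && all(table(gd$group) >= 2L)) {
      cmp <- compare_groups(gd)
      write_comparison(cmp, pth("comparison.csv"), pth("report.txt"))
      add("comparison.csv"); add("report.txt")
      log_stage("stats", t0)
    } else {
      warn("stats stage skipped: need >= 2 groups with >= 2 replicates")
    }
  }

  # manifest with checksums
  cfg_json <- pth("config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  add("config.json")
  sums <- tools::md5sum(file.path(out_dir, sort(unique(products))))
  manifest <- list(
    products = setNames(as.list(unname(sums)), basename(names(sums))),
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  log_stage("done", t0, sprintf("%d products", length(manifest$products)))
  invisible(manifest)
}
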