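# simulate, render with realistic noise, and convert a patchy scene
patch_scene_map <- function(patches, cell_types, t_index = NULL,
                            duration_s = 300, rows = 40, cols = 40,
                            seed = 1L, smoothing = 2, d_eff = 2e-4,
                            all_maps = FALSE) {
  sc <- scene_spec(c(rows, cols), 0.1, cell_types = cell_types,
                   patches = patches,
                   chamber = list(D_eff_mm2_per_s = d_eff))
  acq <- noisy_acq(interval_s = 20, duration_s = duration_s, seed = seed)
  cal <- demo_o2_cal()
  maps <- simulate_fields(sc, acq, "O2")
  stack <- render_frames(maps, cal, acq)
  convert <- function(t) {
    apply_calibration(smooth_map(compute_ratio(stack, t), smoothing), cal)
  }
  if (all_maps) {
    lapply(seq_along(maps), convert)
  } else {
    convert(t_index %||% length(maps))
  }
}

test_that("a uniform map contains no active regions", {
  m <- analyte_map(matrix(95, 30, 30), "O2", 0.1)
  rs <- detect_active_regions(m, detection_params())
  expect_equal(nrow(rs$regions), 0L)
  expect_true(all(rs$labels == 0L))
  expect_error(detect_active_regions(analyte_map(matrix(NaN, 5, 5), "O2", 0.1)),
               "valid")
})

test_that("a single metabolically active patch is found with IoU >= 0.5", {
  truth <- matrix(FALSE, 40, 40); truth[13:27, 13:27] <- TRUE
  m <- patch_scene_map(list(rect_patch(13:27, 13:27, "t")),
                       list(t = cell_type(66000, k_o2 = 7.6e-7)),
                       t_index = 31, duration_s = 600)  # 10 min
  rs <- detect_active_regions(m, detection_params())
  expect_equal(nrow(rs$regions), 1L)
  expect_gte(optomet:::iou(rs$labels == 1L, truth), 0.5)
})

test_that("patches separated beyond the smoothing scale remain two regions", {
  m <- patch_scene_map(list(rect_patch(5:14, 5:14, "t"),
                            rect_patch(26:35, 26:35, "t")),
                       list(t = cell_type(66000, k_o2 = 7.6e-7)),
                       t_index = 31, duration_s = 600)
  rs <- detect_active_regions(m, detection_params())
  expect_equal(nrow(rs$regions), 2L)
})

test_that("raising the detection threshold never grows the detected area", {
  m <- patch_scene_map(list(rect_patch(13:27, 13:27, "t")),
                       list(t = cell_type(66000, k_o2 = 7.6e-7)),
                       t_index = 10)
  areas <- vapply(c(2, 5, 10, 20), function(k) {
    rs <- detect_active_regions(m, detection_params(k = k, min_area_mm2 = 0))
    sum(rs$regions$area_mm2)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("detection is translation-equivariant", {
  # noise-free variant: the detection mask is a deterministic function of the
  # scene, so shifting the patch by 10 rows shifts the mask by 10 rows
  mk <- function(r0) {
    sc <- scene_spec(c(40, 40), 0.1,
                     cell_types = list(t = cell_type(66000, k_o2 = 7.6e-7)),
                     patches = list(rect_patch(r0:(r0 + 9), 8:17, "t")))
    acq <- acquisition_spec(20, 120)
    cal <- demo_o2_cal()
    stack <- render_frames(simulate_fields(sc, acq, "O2"), cal, acq)
    apply_calibration(smooth_map(compute_ratio(stack, 7L), 2), cal)
  }
  rs_a <- detect_active_regions(mk(10), detection_params())
  rs_b <- detect_active_regions(mk(20), detection_params())
  expect_equal((rs_a$labels > 0)[4:25, ], (rs_b$labels > 0)[14:35, ])
  expect_equal(nrow(rs_a$regions), 1L)
})

test_that("time to detection reflects metabolic density", {
  truth <- matrix(FALSE, 40, 40); truth[13:27, 13:27] <- TRUE
  mk_maps <- function(density) {
    patch_scene_map(list(rect_patch(13:27, 13:27, "t")),
                    list(t = cell_type(density, k_o2 = 7.6e-7)),
                    duration_s = 600, all_maps = TRUE, seed = 2L)
  }
  t_hi <- time_to_detection(mk_maps(2 * 66000), truth, detection_params())
  t_lo <- time_to_detection(mk_maps(66000), truth, detection_params())
  expect_lte(t_hi, t_lo)

  # zero consumption is never detected
  t_none <- time_to_detection(mk_maps(0), truth, detection_params())
  expect_true(is.na(t_none))

  # a patch below the area gate is never detected, regardless of depth
  small_truth <- matrix(FALSE, 40, 40); small_truth[20:21, 20:21] <- TRUE
  small <- patch_scene_map(list(rect_patch(20:21, 20:21, "t")),
                           list(t = cell_type(2e5, k_o2 = 7.6e-7)),
                           duration_s = 600, all_maps = TRUE, seed = 3L)
  expect_true(is.na(time_to_detection(small, small_truth,
                                      detection_params(min_area_mm2 = 0.5))))
})

test_that("longer measurements detect sparser cell layers", {
  truth <- matrix(FALSE, 40, 40); truth[13:27, 13:27] <- TRUE
  detected_at <- function(density, t_index) {
    maps <- patch_scene_map(list(rect_patch(13:27, 13:27, "t")),
                            list(t = cell_type(density, k_o2 = 7.6e-7)),
                            duration_s = 3600, all_maps = TRUE, seed = 4L,
                            d_eff = 0)
    sub <- maps[seq_len(t_index)]
    !is.na(time_to_detection(sub, truth, detection_params()))
  }
  densities <- c(5000, 20000, 66000)
  at_10min <- vapply(densities, detected_at, logical(1), t_index = 31L)
  at_60min <- vapply(densities, detected_at, logical(1), t_index = 181L)
  # everything detectable early stays detectable late, and the longer
  # measurement reaches at least as far down the density ladder
  expect_true(all(at_60min >= at_10min))
  expect_gte(sum(at_60min), sum(at_10min))
})

test_that("areal density conversion matches the printed detection limits", {
  d1 <- areal_density(2000, 0.03, "floor_thousand")
  expect_equal(as.numeric(d1), 66000)
  expect_equal(attr(d1, "rounding"), "floor_thousand")
  expect_equal(as.numeric(areal_density(2000, 0.03)), 66666.66667,
               tolerance = 1e-9)
  expect_equal(as.numeric(areal_density(6000, 0.03)), 200000)
  expect_equal(as.numeric(areal_density(0, 0.03)), 0)
  expect_error(areal_density(100, 0), "> 0")
})

test_that("region tables serialise with the documented columns", {
  m <- patch_scene_map(list(rect_patch(13:27, 13:27, "t")),
                       list(t = cell_type(66000, k_o2 = 7.6e-7)),
                       t_index = 10)
  rs <- detect_active_regions(m, detection_params())
  p <- withr::local_tempfile(fileext = ".csv")
  write_regions_csv(rs, p)
  df <- utils::read.csv(p)
  expect_named(df, c("region_id", "area_mm2", "mean_depression",
                     "centroid_x", "centroid_y"))
  expect_equal(nrow(df), nrow(rs$regions))
})
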