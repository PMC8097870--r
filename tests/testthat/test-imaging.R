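make_stack <- function(sens, ref, pixel_size_mm = 0.1) {
  t_len <- 1L
  fr <- array(0, c(t_len, nrow(sens), ncol(sens), 2L))
  fr[1, , , 1] <- sens
  fr[1, , , 2] <- ref
  frame_stack(fr, 0, pixel_size_mm = pixel_size_mm)
}

test_that("ratio computation divides channels and guards the reference", {
  sens <- matrix(200, 8, 8); ref <- matrix(100, 8, 8)
  rm_ <- compute_ratio(make_stack(sens, ref), 1L)
  expect_equal(rm_$values, matrix(2, 8, 8))

  # common-mode illumination cancels
  l_field <- matrix(runif(64, 0.5, 2), 8, 8)
  rm2 <- compute_ratio(make_stack(sens * l_field, ref * l_field), 1L)
  expect_equal(rm2$values, matrix(2, 8, 8), tolerance = 1e-12)

  # zero reference pixel -> NaN there, finite elsewhere
  ref0 <- ref; ref0[3, 4] <- 0
  rm3 <- compute_ratio(make_stack(sens, ref0), 1L)
  expect_true(is.nan(rm3$values[3, 4]))
  expect_equal(rm3$flags[3, 4], optomet:::FLAG_INVALID)
  expect_equal(sum(is.nan(rm3$values)), 1L)

  expect_error(compute_ratio(make_stack(sens, ref), 5L), "out of range")
})

test_that("gaussian smoothing preserves constants, mass and the identity case", {
  const <- ratio_map(matrix(3.2, 20, 20), 0.1)
  expect_equal(smooth_map(const, 2)$values, const$values, tolerance = 1e-12)

  imp <- matrix(0, 31, 31); imp[16, 16] <- 10
  sm <- smooth_map(ratio_map(imp, 0.1), 2)
  expect_equal(sum(sm$values), 10, tolerance = 1e-6)

  noisy <- ratio_map(matrix(rnorm(100, 2), 10, 10), 0.1)
  expect_identical(smooth_map(noisy, 0), noisy)
  expect_error(smooth_map(noisy, -1), ">= 0")
})

test_that("smoothing excludes invalid pixels via normalised convolution", {
  v <- matrix(5, 15, 15)
  v[8, 8] <- NaN
  sm <- smooth_map(ratio_map(v, 0.1), 1.5)
  # neighbours of the hole keep the constant value instead of bleeding NaN/0
  expect_equal(sm$values[8, 9], 5, tolerance = 1e-9)
  expect_true(is.nan(sm$values[8, 8]))
  expect_equal(sm$flags[8, 8], optomet:::FLAG_INVALID)
})

test_that("calibration application inverts ratios and propagates flags", {
  cal <- demo_o2_cal()
  rm_ <- ratio_map(matrix(cal$r0, 5, 5), 0.1)
  am <- apply_calibration(rm_, cal)
  expect_equal(am$values, matrix(0, 5, 5))
  expect_equal(am$analyte, "O2")

  v <- matrix(0.8, 4, 4); v[2, 2] <- NaN
  am2 <- apply_calibration(ratio_map(v, 0.1), cal)
  expect_true(is.nan(am2$values[2, 2]))
  expect_equal(am2$flags[2, 2], optomet:::FLAG_INVALID)
  expect_warning(apply_calibration(
    ratio_map(v, 0.1),
    fit_o2_calibration(calibration_table(c(0, 100), c(1.6, 0.4)), "batchA"),
    batch_id = "batchB"), "batch")
})

test_that("simulate -> render -> ratio -> calibrate reproduces the field", {
  cal <- demo_o2_cal()
  sc <- scene_spec(c(16, 16), 0.1,
                   cell_types = list(t = cell_type(66000, k_o2 = 7.6e-7)),
                   patches = list(rect_patch(4:10, 5:12, "t")),
                   chamber = list(D_eff_mm2_per_s = 2e-4))
  acq <- acquisition_spec(20, 300)
  maps <- simulate_fields(sc, acq, "O2")
  stack <- render_frames(maps, cal, acq)
  for (t in seq_along(maps)) {
    rec <- apply_calibration(compute_ratio(stack, t), cal)
    expect_lt(max(abs(rec$values - maps[[t]]$values)), 1e-6)
  }
})

test_that("smoothing before vs after calibration differ (order is fixed)", {
  cal <- demo_o2_cal()
  v <- matrix(seq(0.5, 1.5, length.out = 144), 12, 12)
  rm_ <- ratio_map(v, 0.1)
  a <- apply_calibration(smooth_map(rm_, 2), cal)$values
  b <- smooth_map(apply_calibration(rm_, cal), 2)$values
  expect_gt(max(abs(a - b)), 1e-3)  # nonlinear inversion does not commute
})

test_that("one-point adjustment corrects a biased uniform plate", {
  # uniform truth in ratio space
  truth <- 1.2
  bias <- matrix(1, 16, 24); bias[, 13:24] <- 1.15
  observed <- ratio_map(truth * bias, 0.1)
  field <- fit_illumination(observed, truth)
  expect_equal(field$correction[1, 1], 1)
  expect_equal(field$correction[1, 20], 1 / 1.15, tolerance = 1e-12)

  # identity field leaves a map unchanged
  ident <- fit_illumination(ratio_map(matrix(truth, 16, 24), 0.1), truth)
  other <- ratio_map(matrix(runif(16 * 24, 0.5, 1.5), 16, 24), 0.1)
  expect_equal(apply_opa(other, ident)$values, other$values)

  # correcting a second biased plate recovers the unbiased one
  second <- ratio_map(0.9 * bias, 0.1)
  corrected <- apply_opa(second, field)
  expect_equal(corrected$values, matrix(0.9, 16, 24), tolerance = 1e-12)

  # median anchor: expected set to the observed median gives median factor 1
  # (odd pixel count with a continuous bias so the median is a data value)
  cont <- ratio_map(matrix(seq(1.0, 1.5, length.out = 15 * 21), 15, 21), 0.1)
  anchored <- fit_illumination(cont, median(cont$values))
  expect_equal(median(anchored$correction), 1)

  expect_error(apply_opa(ratio_map(matrix(1, 4, 4), 0.1), field), "shape")
  expect_error(fit_illumination(ratio_map(matrix(c(1, -1), 4, 4), 0.1), 1),
               "> 0")
  expect_error(fit_illumination(observed, 10 * truth), "sanity")
})

test_that("ROI time series averages valid pixels and flags gaps", {
  mk <- function(v, t) analyte_map(v, "O2", 0.1, t)
  const_maps <- lapply(0:4, function(t) mk(matrix(7.5, 6, 6), t * 10))
  roi <- matrix(TRUE, 6, 6)
  ts <- extract_roi_timeseries(const_maps, roi)
  expect_equal(ts$value, rep(7.5, 5))
  expect_equal(ts$time_s, seq(0, 40, 10))
  expect_false(any(ts$gap))

  # half-a / half-b map, ROI over the a half
  v <- matrix(2, 6, 6); v[, 4:6] <- 9
  roi_a <- matrix(FALSE, 6, 6); roi_a[, 1:3] <- TRUE
  ts2 <- extract_roi_timeseries(list(mk(v, 0)), roi_a)
  expect_equal(ts2$value, 2)

  # fully invalid timepoint becomes a flagged gap, not a dropped row
  v_bad <- matrix(NaN, 6, 6)
  ts3 <- extract_roi_timeseries(list(mk(v, 0), mk(v_bad, 10)), roi_a)
  expect_equal(nrow(ts3), 2L)
  expect_true(ts3$gap[2])
  expect_true(is.na(ts3$value[2]))

  expect_error(extract_roi_timeseries(const_maps, matrix(FALSE, 6, 6)),
               "empty")
})

test_that("well extraction recovers per-well constants in A1..H12 order", {
  lay <- grid_plate_layout(c(80, 120), n_rows = 8, n_cols = 12)
  v <- matrix(0, 80, 120)
  truth <- matrix(seq_len(96), 8, 12, byrow = TRUE)
  for (w in seq_len(96)) {
    disc <- optomet:::well_disc_mask(c(80, 120), lay$centers$y_px[w],
                                     lay$centers$x_px[w], lay$radius_px)
    v[disc] <- truth[((w - 1) %/% 12) + 1, ((w - 1) %% 12) + 1]
  }
  wells <- extract_wells(analyte_map(v, "O2", 0.1), lay)
  expect_equal(wells$well[1], "A1")
  expect_equal(wells$well[96], "H12")
  expect_equal(wells$value, as.vector(t(truth)))

  # fully-NaN well -> NA with zero valid pixels
  disc1 <- optomet:::well_disc_mask(c(80, 120), lay$centers$y_px[1],
                                    lay$centers$x_px[1], lay$radius_px)
  v2 <- v; v2[disc1] <- NaN
  wells2 <- extract_wells(analyte_map(v2, "O2", 0.1), lay)
  expect_true(is.na(wells2$value[1]))
  expect_equal(wells2$n_valid[1], 0L)

  off <- plate_layout(1, 2, tibble::tibble(x_px = c(10, 500), y_px = c(10, 10)), 4)
  expect_error(extract_wells(analyte_map(v, "O2", 0.1), off), "outside")
  expect_error(grid_plate_layout(c(10, 10), 8, 12), "outside|overlap")
})

test_that("heat maps render deterministically with pinned colour range", {
  m <- analyte_map(matrix(seq(0, 100, length.out = 64), 8, 8), "O2", 0.1)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(m, p1, range = c(0, 100))
  render_heatmap(m, p2, range = c(0, 100))
  expect_identical(readBin(p1, "raw", 1e6), readBin(p2, "raw", 1e6))

  # constant map renders a single colour
  cm <- analyte_map(matrix(40, 8, 8), "O2", 0.1)
  rgb <- render_heatmap(cm, p1, range = c(0, 100), colorbar = FALSE)
  expect_equal(length(unique(as.vector(rgb[, , 1]))), 1L)

  # min/max pin to the palette endpoints
  pal <- t(grDevices::col2rgb(grDevices::hcl.colors(256, "viridis"))) / 255
  rgb2 <- render_heatmap(m, p1, range = c(0, 100), colorbar = FALSE)
  expect_equal(as.numeric(rgb2[1, 1, ]), as.numeric(pal[1, ]))    # value 0
  expect_equal(as.numeric(rgb2[8, 8, ]), as.numeric(pal[256, ]))  # value 100
})

test_that("mask outlines overlay as one-pixel rectangles", {
  m <- analyte_map(matrix(50, 20, 20), "O2", 0.1)
  mask <- matrix(FALSE, 20, 20); mask[5:12, 6:14] <- TRUE
  rgb <- overlay_outline(m, mask, colours = "white", range = c(0, 100))
  white <- rgb[, , 1] == 1 & rgb[, , 2] == 1 & rgb[, , 3] == 1
  # outline = mask minus its erosion: the rectangle's boundary ring
  ring <- mask
  ring[6:11, 7:13] <- FALSE
  expect_equal(white, ring)

  # empty mask leaves the plain heat map
  plain <- overlay_outline(m, matrix(FALSE, 20, 20), range = c(0, 100))
  expect_equal(plain, optomet:::map_to_rgb(m$values, c(0, 100)))
  expect_error(overlay_outline(m, matrix(TRUE, 5, 5)), "shape")
})

test_that("ROI masks round-trip through 8-bit TIFF", {
  mask <- matrix(FALSE, 12, 12); mask[3:7, 4:9] <- TRUE
  p <- withr::local_tempfile(fileext = ".tif")
  write_roi_mask(roi_mask(mask, "layer"), p)
  back <- read_roi_mask(p)
  expect_equal(back$mask, mask)
})
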