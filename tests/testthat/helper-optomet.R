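# shared fixtures for the test suite; everything is generated in code

# standard two-point oxygen calibration (R0 = 1.6, Ksv = 0.03)
demo_o2_cal <- function() {
  fit_o2_calibration(calibration_table(c(0, 100), c(1.60, 0.40)))
}

# ground-truth pH calibration used as the simulation truth
demo_ph_truth <- function(r_acid = 0.5, r_base = 2.0, pka = 7.0, s = 1) {
  structure(list(r_acid = r_acid, r_base = r_base, pka = pka, s = s,
                 batch_id = "", ph_range = c(5, 8.5)),
            class = "ph_calibration")
}

# uniform monolayer scene: one cell type covering the whole grid
uniform_scene <- function(rows = 30, cols = 30, density = 66000,
                          k_o2 = 7.6e-7, k_ph = 0, pixel_size_mm = 0.1,
                          d_eff = 0) {
  scene_spec(c(rows, cols), pixel_size_mm,
             cell_types = list(cells = cell_type(density, k_o2 = k_o2,
                                                 k_ph = k_ph)),
             patches = list(rect_patch(1:rows, 1:cols, "cells")),
             chamber = list(height_mm = 0.1, reference_height_mm = 0.1,
                            D_eff_mm2_per_s = d_eff))
}

# realistic camera noise used by the noisy-recovery experiments
noisy_acq <- function(interval_s = 20, duration_s = 600, seed = 1L) {
  acquisition_spec(interval_s, duration_s, read_noise_sd = 5,
                   shot_noise = TRUE, seed = seed)
}

# greedy nearest-neighbour centroid matching; with spots far apart relative
# to `max_dist` this equals the optimal assignment
match_centroids <- function(truth, detected, max_dist) {
  if (nrow(truth) == 0L || nrow(detected) == 0L) {
    return(list(n_matched = 0L, max_err = NA_real_))
  }
  d <- sqrt(outer(truth$x_px, detected$x_px, "-")^2 +
              outer(truth$y_px, detected$y_px, "-")^2)
  used <- rep(FALSE, nrow(detected))
  errs <- numeric(0)
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (is.finite(d[i, j]) && d[i, j] <= max_dist && !used[j]) {
      used[j] <- TRUE
      errs <- c(errs, d[i, j])
    }
  }
  list(n_matched = length(errs),
       max_err = if (length(errs)) max(errs) else NA_real_)
}

# fixture: n well-separated Gaussian nuclei on an inset patch, so no spot is
# truncated by the image border
well_separated_nuclei <- function(seed, n = 50, sigma = 3) {
  # inset patch: 24x24 sim px of a 30x30 grid; density chosen so that
  # round(density * patch_area_cm2) == n
  patch_area_cm2 <- 24 * 24 * (0.1 / 10)^2
  sc <- scene_spec(c(30, 30), 0.1,
                   cell_types = list(t = cell_type(n / patch_area_cm2,
                                                   nucleus_radius_px = sigma)),
                   patches = list(rect_patch(4:27, 4:27, "t")))
  acq <- acquisition_spec(20, 20, read_noise_sd = 5, seed = seed)
  render_nuclei_image(sc, acq, pixel_size_mm = 0.01,
                      min_separation_px = 4 * sigma)
}

# fixture: two Gaussian spots whose threshold masks merge into one blob but
# whose separation (1.5 x the visible spot radius) leaves two clear peaks
two_spot_image <- function(sigma = 3, amplitude = 10000, threshold = 500) {
  r_vis <- sigma * sqrt(2 * log(amplitude / threshold))
  sep <- 1.5 * r_vis
  img <- matrix(0, 60, 60)
  rs <- 1:60
  for (xc in c(30 - sep / 2, 30 + sep / 2)) {
    img <- img + amplitude * outer(exp(-(rs - 30)^2 / (2 * sigma^2)),
                                   exp(-(rs - xc)^2 / (2 * sigma^2)))
  }
  matrix(as.integer(round(img + 500)), 60, 60)
}

# brute-force linear-range oracle: all O(T^2) windows via lm()
oracle_linear_range <- function(ts, r2_threshold = 0.99, min_fraction = 0.3,
                                min_points = 10L) {
  t_len <- nrow(ts)
  l_min <- max(min_points, ceiling(min_fraction * t_len))
  best <- NULL
  for (len in t_len:l_min) {
    for (start in seq_len(t_len - len + 1L)) {
      idx <- start:(start + len - 1L)
      fit <- stats::lm(value ~ time_s, data = ts[idx, ])
      r2 <- summary(fit)$r.squared
      if (r2 >= r2_threshold) return(c(start, start + len - 1L))
    }
  }
  NULL  # no qualifying window
}
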