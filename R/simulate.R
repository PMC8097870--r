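#' Simulate the analyte field of a micro-respirator scene
#'
#' Integrates the effective 2-D reaction-diffusion model
#' \deqn{\partial F/\partial t = D_{eff}\nabla^2 F - k\,\rho(x)\,h_{ref}/h}
#' on the scene grid with zero-flux (Neumann) boundaries, by forward Euler
#' with automatic sub-stepping to satisfy the explicit stability bound
#' `dt <= dx^2 / (4 D_eff)`. The oxygen field is clipped at 0 (full local
#' depletion); pH is an unclipped deviation field with buffering folded into
#' the acidification coefficient.
#'
#' @param spec A [scene_spec()].
#' @param acq An [acquisition_spec()]; one map is produced per acquisition
#'   timestamp `0, interval_s, ..., <= duration_s`.
#' @param analyte `"O2"` or `"pH"`.
#' @param max_substeps Maximum Euler sub-steps per acquisition interval;
#'   exceeding it is a configuration error.
#' @param initial_field Optional matrix overriding the uniform initial
#'   condition (useful for studying pure diffusion of a structured field).
#' @return List of [analyte_map()]s, one per timestamp.
#' @examples
#' sc <- scene_spec(c(20, 20), 0.1,
#'                  cell_types = list(t = cell_type(66000, k_o2 = 7.6e-7)),
#'                  patches = list(rect_patch(6:15, 6:15, "t")))
#' maps <- simulate_fields(sc, acquisition_spec(60, 300), "O2")
#' maps[[6]]
#' @export
simulate_fields <- function(spec, acq, analyte = c("O2", "pH"),
                            max_substeps = 100000L, initial_field = NULL) {
  stopifnot(inherits(spec, "scene_spec"), inherits(acq, "acquisition_spec"))
  analyte <- match.arg(analyte)
  sink <- sink_rate_map(spec, analyte)
  d <- spec$chamber$D_eff_mm2_per_s
  dx <- spec$pixel_size_mm
  times <- acq_timestamps(acq)

  if (d > 0) {
    dt_max <- dx^2 / (4 * d)
    n_sub <- ceiling(acq$interval_s / dt_max)
  } else {
    n_sub <- 1L
  }
  if (n_sub > max_substeps) {
    abort(sprintf(
      "stability requires %d sub-steps per interval (max_substeps = %d); reduce D_eff or enlarge pixels",
      n_sub, max_substeps))
  }
  dt <- acq$interval_s / n_sub

  f0 <- if (analyte == "O2") spec$initial_o2_pct else spec$initial_ph
  f <- if (is.null(initial_field)) {
    matrix(f0, spec$grid_shape[1L], spec$grid_shape[2L])
  } else {
    stopifnot(all(dim(initial_field) == spec$grid_shape))
    initial_field
  }
  out <- vector("list", length(times))
  out[[1L]] <- analyte_map(f, analyte, dx, times[1L])
  for (ti in seq_along(times)[-1L]) {
    for (s in seq_len(n_sub)) {
      if (d > 0) f <- f + dt * d * laplacian_neumann(f, dx)
      f <- f - dt * sink
      if (analyte == "O2") f[f < 0] <- 0
    }
    out[[ti]] <- analyte_map(f, analyte, dx, times[ti])
  }
  out
}

# 5-point Laplacian with zero-flux boundaries (edge replication)
laplacian_neumann <- function(f, dx) {
  nr <- nrow(f); nc <- ncol(f)
  up <- f[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down <- f[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  left <- f[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- f[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (up + down + left + right - 4 * f) / dx^2
}
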