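#' Build a calibration table
#'
#' @param analyte Numeric vector of known analyte values (% air saturation
#'   for O2, pH for the pH foil); must be distinct.
#' @param ratio Observed mean sensitive/reference ratio at each value.
#' @param sd Optional ratio SDs.
#' @return Tibble with class `calibration_table`.
#' @export
calibration_table <- function(analyte, ratio, sd = NULL) {
  if (anyDuplicated(analyte)) abort("analyte values must be distinct")
  if (length(analyte) != length(ratio)) abort("`analyte` and `ratio` lengths differ")
  out <- tibble(analyte = as.numeric(analyte), ratio = as.numeric(ratio))
  if (!is.null(sd)) out$sd <- as.numeric(sd)
  class(out) <- c("calibration_table", class(out))
  out
}

#' Read / write calibration tables as CSV
#'
#' CSV contract: columns `analyte,ratio[,sd]`.
#' @param path File path.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  calibration_table(df$analyte, df$ratio, df$sd)
}

#' @rdname read_calibration_table
#' @param table A [calibration_table()].
#' @export
write_calibration_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit a Stern-Volmer oxygen calibration
#'
#' The oxygen foil follows collisional quenching,
#' \eqn{R(C) = R_0 / (1 + K_{sv} C)}, with `C` in % air saturation. Two
#' points (classically a 0% sulfite standard and air-saturated medium at
#' 100%) determine the model in closed form; with more points the model,
#' linear in `C` on the `1/R` scale, is fitted by least squares.
#'
#' @param table A [calibration_table()] with >= 2 distinct points.
#' @param batch_id Optional sensor-foil batch identifier; each foil batch is
#'   calibrated separately.
#' @return An `o2_calibration` object with fields `r0`, `ksv`.
#' @examples
#' cal <- fit_o2_calibration(calibration_table(c(0, 100), c(1.60, 0.40)))
#' cal$r0   # 1.60
#' cal$ksv  # 0.03
#' @export
fit_o2_calibration <- function(table, batch_id = "") {
  if (nrow(table) < 2L) abort("O2 calibration needs >= 2 points")
  if (any(table$ratio <= 0) || any(!is.finite(table$ratio))) {
    abort("calibration ratios must be positive")
  }
  if (any(table$analyte < 0)) abort("analyte values must be >= 0 (% air sat)")
  # 1/R = 1/R0 + (Ksv/R0) C  — exact for 2 points, least squares beyond
  if (nrow(table) == 2L) {
    o <- order(table$analyte)
    c1 <- table$analyte[o[1L]]; c2 <- table$analyte[o[2L]]
    r1 <- table$ratio[o[1L]]; r2 <- table$ratio[o[2L]]
    slope <- (1 / r2 - 1 / r1) / (c2 - c1)
    intercept <- 1 / r1 - slope * c1
  } else {
    fit <- lm(I(1 / ratio) ~ analyte, data = table)
    intercept <- coef(fit)[[1L]]
    slope <- coef(fit)[[2L]]
  }
  if (intercept <= 0) abort("calibration fit implies non-positive R0")
  r0 <- 1 / intercept
  ksv <- slope / intercept
  if (ksv <= 0) abort("no quenching: ratio does not decrease with O2")
  fitted_ratio <- r0 / (1 + ksv * table$analyte)
  structure(list(r0 = r0, ksv = ksv, batch_id = batch_id,
                 n_points = nrow(table),
                 residual_norm = sqrt(sum((fitted_ratio - table$ratio)^2))),
            class = "o2_calibration")
}

#' Forward calibration model: analyte value to expected ratio
#'
#' @param cal An `o2_calibration` or `ph_calibration`.
#' @param value Analyte values (% air saturation or pH).
#' @return Expected sensitive/reference ratios.
#' @export
predict_ratio <- function(cal, value) UseMethod("predict_ratio")

#' @export
predict_ratio.o2_calibration <- function(cal, value) {
  cal$r0 / (1 + cal$ksv * value)
}

#' @export
predict_ratio.ph_calibration <- function(cal, value) {
  cal$r_acid + (cal$r_base - cal$r_acid) /
    (1 + 10^(cal$s * (cal$pka - value)))
}

#' Invert an oxygen calibration: ratio to % air saturation
#'
#' Ratios above `R0` (possible transiently through noise) clamp to 0% with a
#' `clamped` attribute rather than erroring; `NaN` propagates.
#'
#' @param ratio Positive ratio values.
#' @param cal An `o2_calibration`.
#' @return Numeric vector of % air saturation with logical attribute
#'   `clamped`.
#' @export
ratio_to_po2 <- function(ratio, cal) {
  stopifnot(inherits(cal, "o2_calibration"))
  if (any(ratio <= 0, na.rm = TRUE)) abort("ratios must be > 0")
  out <- (cal$r0 / ratio - 1) / cal$ksv
  clamped <- is.finite(out) & out < 0
  out[clamped] <- 0
  attr(out, "clamped") <- clamped
  out
}

#' Fit a sigmoid pH calibration
#'
#' The pH foil response is modelled as a 4-parameter log-sigmoid,
#' \eqn{R(pH) = R_{acid} + (R_{base} - R_{acid}) / (1 + 10^{s (pK_a - pH)})},
#' fitted by nonlinear least squares to >= 4 buffer points (standard practice
#' uses six buffers between pH 5 and 8.5 at 40 mM buffer capacity). Starting
#' values come from the extreme points (asymptotes), the mid-ratio crossing
#' (pKa) and `s = 1`. Fit failure or a non-monotone fitted curve on [5, 8.5]
#' is a calibration error.
#'
#' @inheritParams fit_o2_calibration
#' @return A `ph_calibration` object with fields `r_acid`, `r_base`, `pka`,
#'   `s` and the calibrated pH range.
#' @export
fit_ph_calibration <- function(table, batch_id = "") {
  if (nrow(table) < 4L) abort("pH calibration needs >= 4 points")
  if (any(!is.finite(table$ratio))) abort("non-finite ratios in table")
  o <- order(table$analyte)
  ph <- table$analyte[o]; r <- table$ratio[o]
  r_acid0 <- r[1L]; r_base0 <- r[length(r)]
  if (r_acid0 == r_base0) abort("degenerate table: flat response")
  mid <- (r_acid0 + r_base0) / 2
  pka0 <- stats::approx(r, ph, xout = mid, ties = mean)$y
  if (is.na(pka0)) pka0 <- stats::median(ph)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ r_acid + (r_base - r_acid) / (1 + 10^(s * (pka - analyte))),
      data = table,
      start = list(r_acid = r_acid0, r_base = r_base0, pka = pka0, s = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste("pH calibration fit failed:", conditionMessage(e))))
  p <- as.list(coef(fit))
  cal <- structure(list(r_acid = p$r_acid, r_base = p$r_base, pka = p$pka,
                        s = p$s, batch_id = batch_id,
                        ph_range = range(table$analyte),
                        n_points = nrow(table),
                        residual_norm = sqrt(sum(stats::resid(fit)^2))),
                   class = "ph_calibration")
  grid <- seq(5, 8.5, length.out = 200)
  dr <- diff(predict_ratio(cal, grid))
  if (!(all(dr > 0) || all(dr < 0))) {
    abort(sprintf(
      "fitted pH response is not strictly monotone on [5, 8.5] (s = %.3g, residual norm %.3g)",
      p$s, cal$residual_norm))
  }
  cal
}

#' Invert a pH calibration: ratio to pH
#'
#' Ratios outside the open interval between the two asymptotes clamp to the
#' nearest calibrated endpoint pH with a `clamped` attribute; `NaN`
#' propagates.
#'
#' @param ratio Ratio values.
#' @param cal A `ph_calibration`.
#' @return Numeric pH vector with logical attribute `clamped`.
#' @export
ratio_to_ph <- function(ratio, cal) {
  stopifnot(inherits(cal, "ph_calibration"))
  lo <- min(cal$r_acid, cal$r_base); hi <- max(cal$r_acid, cal$r_base)
  out <- rep(NA_real_, length(ratio))
  clamped <- rep(FALSE, length(ratio))
  inside <- is.finite(ratio) & ratio > lo & ratio < hi
  out[inside] <- cal$pka -
    (1 / cal$s) * log10((cal$r_base - ratio[inside]) / (ratio[inside] - cal$r_acid))
  # beyond the base-side asymptote -> high-pH endpoint (for s > 0), etc.
  base_is_high_ph <- cal$s > 0
  at_base <- is.finite(ratio) & !inside &
    (abs(ratio - cal$r_base) <= abs(ratio - cal$r_acid))
  at_acid <- is.finite(ratio) & !inside & !at_base
  out[at_base] <- if (base_is_high_ph) cal$ph_range[2L] else cal$ph_range[1L]
  out[at_acid] <- if (base_is_high_ph) cal$ph_range[1L] else cal$ph_range[2L]
  clamped[at_base | at_acid] <- TRUE
  out[is.nan(ratio)] <- NaN
  attr(out, "clamped") <- clamped
  out
}

# shared inversion used by apply_calibration(); returns values + flag matrix
invert_ratio <- function(values, cal) {
  flags <- matrix(FLAG_OK, nrow(values), ncol(values))
  v <- as.vector(values)
  bad <- !is.finite(v)
  v[bad] <- NA_real_
  v[v <= 0 & !is.na(v)] <- NA_real_
  if (inherits(cal, "o2_calibration")) {
    res <- ratio_to_po2(pmax(v, .Machine$double.eps), cal)
  } else {
    res <- ratio_to_ph(v, cal)
  }
  clamped <- attr(res, "clamped")
  out <- matrix(as.numeric(res), nrow(values), ncol(values))
  out[matrix(bad | is.na(v), nrow(values))] <- NaN
  flags[matrix(clamped, nrow(values))] <- FLAG_CLAMPED
  flags[!is.finite(out)] <- FLAG_INVALID
  list(values = out, flags = flags)
}

#' Serialise a calibration to a JSON sidecar file
#'
#' Records the model name, parameters, residual norm and foil batch ID.
#' @param cal An `o2_calibration` or `ph_calibration`.
#' @param path Output file.
#' @export
write_calibration <- function(cal, path) {
  model <- if (inherits(cal, "o2_calibration")) "stern_volmer" else "log_sigmoid_4p"
  obj <- c(list(model = model), unclass(cal))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- obj$model
  obj$model <- NULL
  cls <- if (model == "stern_volmer") "o2_calibration" else "ph_calibration"
  structure(obj, class = cls)
}

#' @export
print.o2_calibration <- function(x, ...) {
  cat(sprintf("<o2_calibration R0 = %.4g, Ksv = %.4g per %% air sat%s>\n",
              x$r0, x$ksv,
              if (nzchar(x$batch_id)) paste0(", batch ", x$batch_id) else ""))
  invisible(x)
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("<ph_calibration R_acid = %.4g, R_base = %.4g, pKa = %.4g, s = %.4g>\n",
              x$r_acid, x$r_base, x$pka, x$s))
  invisible(x)
}

#' Tidy calibration parameters
#' @param x A fitted calibration.
#' @param ... Unused.
#' @method tidy o2_calibration
#' @export
tidy.o2_calibration <- function(x, ...) {
  tibble(term = c("r0", "ksv"), estimate = c(x$r0, x$ksv))
}

#' @rdname tidy.o2_calibration
#' @method tidy ph_calibration
#' @export
tidy.ph_calibration <- function(x, ...) {
  tibble(term = c("r_acid", "r_base", "pka", "s"),
         estimate = c(x$r_acid, x$r_base, x$pka, x$s))
}

#' One-line calibration fit summary
#' @param x A fitted calibration.
#' @param ... Unused.
#' @method glance o2_calibration
#' @export
glance.o2_calibration <- function(x, ...) {
  tibble(model = "stern_volmer", n_points = x$n_points,
         residual_norm = x$residual_norm, batch_id = x$batch_id)
}

#' @rdname glance.o2_calibration
#' @method glance ph_calibration
#' @export
glance.ph_calibration <- function(x, ...) {
  tibble(model = "log_sigmoid_4p", n_points = x$n_points,
         residual_norm = x$residual_norm, batch_id = x$batch_id)
}
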