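#' Fit a D2O standard curve
#'
#' Ordinary least squares line relating instrument readings from a liquid
#' water isotope analyzer to known D2O fractions:
#' `reading = slope * known_fraction + intercept`. Plasma samples in the
#' workflow are distilled and diluted 1:300 before measurement; whether the
#' standards were diluted identically (so no rescaling is needed at
#' inversion time) is recorded downstream, not here.
#'
#' @param points A data frame with columns `known_fraction` (D2O mole
#'   fraction of the standard, 0-1) and `reading` (instrument response).
#'   At least two distinct `known_fraction` values are required.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `points` and the underlying `lm` fit.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' std <- tibble::tibble(known_fraction = c(0, 0.02, 0.04, 0.06),
#'                       reading = c(0.0002, 0.0201, 0.0403, 0.0601))
#' fit_standard_curve(std)
#' @export
fit_standard_curve <- function(points) {
  points <- as_tibble(points)
  required <- c("known_fraction", "reading")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("Standard-curve table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "fgng_calibration_error")
  }
  points <- points[complete.cases(points[required]), ]
  if (nrow(points) < 2 || length(unique(points$known_fraction)) < 2) {
    abort("Standard curve needs >= 2 points with >= 2 distinct known fractions.",
          class = "fgng_calibration_error")
  }
  fit <- stats::lm(reading ~ known_fraction, data = points)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope == 0) {
    abort("Fitted standard-curve slope is zero or non-finite.",
          class = "fgng_calibration_error")
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$reading - mean(points$reading))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = r2, points = points, fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> reading = %.6g * fraction + %.6g  (n = %d, R^2 = %.5f)\n",
    x$slope, x$intercept, nrow(x$points), x$r_squared))
  invisible(x)
}

#' @rdname fit_standard_curve
#' @param x,object A `standard_curve`.
#' @param ... Unused.
#' @export
tidy.standard_curve <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = unname(co[, 1]),
         std.error = unname(co[, 2]),
         statistic = unname(co[, 3]),
         p.value = unname(co[, 4]))
}

#' @rdname fit_standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         n_points = nrow(x$points))
}

#' Back-calculate body-water enrichment from instrument readings
#'
#' Inverts a fitted standard curve for each sample reading and, when the
#' standards were *not* carried through the same dilution as the samples,
#' multiplies by the dilution factor to recover the undiluted body-water
#' D2O fraction. In the reference workflow both samples and standards pass
#' through the same 1:300 dilution, so the curve is already dilution-aware
#' and no rescaling is applied (`curve_includes_dilution = TRUE`).
#'
#' Back-calculated values in `(-1e-4, 0)` are treated as instrument noise
#' around a true zero: clamped to 0 and flagged. Values at or below `-1e-4`,
#' or above 1 after scaling, indicate a pipeline or unit error and abort.
#'
#' @param curve A fitted [fit_standard_curve()] object.
#' @param readings Data frame with columns `sample_id` and `reading`, or a
#'   bare numeric vector of readings.
#' @param dilution_factor Fold dilution of the distilled samples
#'   (default 300).
#' @param curve_includes_dilution If `TRUE` (default) the standards saw the
#'   same dilution as the samples and the inverted value is already the
#'   body-water fraction.
#' @return A tibble with columns `sample_id`, `enrichment` (fraction 0-1),
#'   `dilution_factor`, `clamped` (logical QC flag).
#' @examples
#' curve <- fit_standard_curve(
#'   tibble::tibble(known_fraction = c(0, 0.06), reading = c(0, 0.06)))
#' enrichment_from_reading(curve, c(a = 0.055))
#' @export
enrichment_from_reading <- function(curve, readings, dilution_factor = 300,
                                    curve_includes_dilution = TRUE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(dilution_factor) || dilution_factor <= 0) {
    abort("`dilution_factor` must be a positive number.",
          class = "fgng_domain_error")
  }
  if (is.numeric(readings)) {
    ids <- names(readings) %||% paste0("sample_", seq_along(readings))
    readings <- tibble(sample_id = ids, reading = unname(readings))
  }
  readings <- as_tibble(readings)
  if (!all(c("sample_id", "reading") %in% names(readings))) {
    abort("`readings` needs columns sample_id and reading.",
          class = "fgng_validation_error")
  }
  x <- (readings$reading - curve$intercept) / curve$slope
  if (!curve_includes_dilution) x <- x * dilution_factor
  too_negative <- x <= -1e-4
  if (any(too_negative)) {
    abort(paste0("Back-calculated enrichment < -1e-4 for sample(s): ",
                 paste(readings$sample_id[too_negative], collapse = ", "),
                 " — check units and curve."),
          class = "fgng_measurement_error")
  }
  clamped <- x < 0
  if (any(clamped)) {
    warn(paste0("Clamped ", sum(clamped),
                " slightly negative enrichment value(s) to 0."))
    x[clamped] <- 0
  }
  if (any(x > 1)) {
    abort("Back-calculated enrichment exceeds 1; readings and curve disagree on scale.",
          class = "fgng_measurement_error")
  }
  tibble(sample_id = readings$sample_id, enrichment = x,
         dilution_factor = dilution_factor, clamped = clamped)
}

#' @rdname fit_standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$known_fraction, y = .data$reading)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Known D2O fraction", y = "Instrument reading",
                  title = sprintf("Standard curve (R² = %.4f)",
                                  object$r_squared))
}
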