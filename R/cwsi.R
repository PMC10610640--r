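#' Convert Kelvin to Celsius
#'
#' @param t Numeric vector of temperatures in Kelvin; must be non-negative
#'   (below absolute zero is rejected).
#' @return Temperatures in degrees Celsius.
#' @examples
#' kelvin_to_celsius(305.05)
#' @export
kelvin_to_celsius <- function(t) {
  if (any(t < 0, na.rm = TRUE)) stop("negative Kelvin temperature")
  t - 273.15
}

#' Wet and dry reference temperatures from the histogram tails
#'
#' The simplified-CWSI reference procedure: the wet reference is the mean of
#' the coolest `tail_fraction` of the canopy temperatures and the dry
#' reference the mean of the warmest `tail_fraction` (default 0.5% each).
#' The tail count is `max(1, round(tail_fraction * N))` with half-away-from-
#' zero rounding, so at least one value enters each tail.
#'
#' @param values Numeric vector of canopy temperatures in degrees Celsius
#'   with no-data already removed; needs at least 2 finite values.
#' @param tail_fraction Proportion of the histogram averaged into each
#'   reference, in (0, 0.5).
#' @return An object of class `reference_temps` with fields `t_wet`, `t_dry`,
#'   `tail_fraction`, `n_tail`.
#' @examples
#' reference_temps(c(31, 33, 35, 37, 42))
#' @export
reference_temps <- function(values, tail_fraction = 0.005) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite with no-data removed beforehand")
  n <- length(values)
  if (n < 2) stop("need at least 2 temperature values, got ", n)
  if (tail_fraction <= 0 || tail_fraction >= 0.5)
    stop("tail_fraction must lie in (0, 0.5)")
  n_tail <- max(1L, round_half_up(tail_fraction * n))
  s <- sort(values)  # stable: ties keep value order
  t_wet <- mean(s[seq_len(n_tail)])
  t_dry <- mean(s[seq.int(n - n_tail + 1L, n)])
  if (t_dry <= t_wet)
    stop("degenerate reference interval: t_dry (", t_dry,
         ") must exceed t_wet (", t_wet, ")")
  structure(list(t_wet = t_wet, t_dry = t_dry,
                 tail_fraction = tail_fraction, n_tail = n_tail),
            class = "reference_temps")
}

# round half away from zero (base round() is half-to-even)
round_half_up <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' @export
print.reference_temps <- function(x, ...) {
  cat(sprintf("<reference_temps> t_wet %.2f degC  t_dry %.2f degC (tail %.2g%%, n_tail %d)\n",
              x$t_wet, x$t_dry, 100 * x$tail_fraction, x$n_tail))
  invisible(x)
}

#' Crop Water Stress Index
#'
#' `CWSI = (T_canopy - T_wet) / (T_dry - T_wet)`, applied elementwise. Values
#' are never clipped: observations cooler than the wet reference give
#' negative CWSI and warmer than the dry reference give CWSI above one; both
#' are retained as flagged outliers (see [cwsi_outlier_fraction()]).
#'
#' Methods exist for plain numeric vectors, [raster_grid()] layers (no-data
#' propagates) and [point_cloud()]s (the result is attached as a `cwsi`
#' scalar field; temperatures in Kelvin are converted first).
#'
#' @param x Canopy temperatures in degrees Celsius, or a raster/cloud
#'   carrying them.
#' @param refs A [reference_temps()].
#' @param ... Passed between methods.
#' @return Same shape as the input: numeric vector, `raster_grid`, or
#'   `point_cloud` with a `cwsi` scalar.
#' @examples
#' refs <- structure(list(t_wet = 31.8, t_dry = 41.9, tail_fraction = 0.005,
#'                        n_tail = 1L), class = "reference_temps")
#' cwsi(34.9, refs)
#' @export
cwsi <- function(x, refs, ...) UseMethod("cwsi")

check_refs <- function(refs) {
  if (!inherits(refs, "reference_temps"))
    stop("refs must be a reference_temps object")
  if (!is.finite(refs$t_wet) || !is.finite(refs$t_dry) ||
      refs$t_dry <= refs$t_wet)
    stop("invalid references: t_dry must exceed t_wet")
  invisible(refs)
}

#' @rdname cwsi
#' @export
cwsi.default <- function(x, refs, ...) {
  check_refs(refs)
  (x - refs$t_wet) / (refs$t_dry - refs$t_wet)
}

#' @rdname cwsi
#' @export
cwsi.raster_grid <- function(x, refs, ...) {
  check_refs(refs)
  out <- x
  out$values <- (x$values - refs$t_wet) / (refs$t_dry - refs$t_wet)
  out
}

#' @rdname cwsi
#' @export
cwsi.point_cloud <- function(x, refs, ...) {
  check_refs(refs)
  if (is.null(x$temperature))
    stop("point cloud carries no temperature attribute")
  t_c <- if (identical(x$temp_unit, "kelvin"))
    kelvin_to_celsius(x$temperature) else x$temperature
  set_scalar(x, "cwsi", (t_c - refs$t_wet) / (refs$t_dry - refs$t_wet))
}

#' Fraction of CWSI values outside the unit interval
#'
#' @param cwsi_values Numeric CWSI values (NA ignored).
#' @return Proportion with CWSI < 0 or > 1.
#' @export
cwsi_outlier_fraction <- function(cwsi_values) {
  v <- cwsi_values[is.finite(cwsi_values)]
  if (!length(v)) return(NA_real_)
  mean(v < 0 | v > 1)
}

#' Summary statistics for a temperature/CWSI sample
#'
#' Min, max, mean and sample standard deviation (n - 1 denominator) of the
#' temperature and CWSI channels, plus the references, sample count, sampling
#' distance, and the out-of-\[0, 1\] CWSI fraction. This is the per-data-model
#' summary a flight comparison table is built from.
#'
#' @param values Temperatures in degrees Celsius.
#' @param cwsi_values CWSI values of the same length.
#' @param refs The [reference_temps()] used.
#' @param spacing Sample spacing in cm (pixel size or mean point distance).
#' @return An object of class `thermal_summary`.
#' @export
summarize_thermal <- function(values, cwsi_values, refs, spacing = NA_real_) {
  values <- values[is.finite(values)]
  cwsi_values <- cwsi_values[is.finite(cwsi_values)]
  if (!length(values) || length(values) != length(cwsi_values))
    stop("need equal, non-empty temperature and CWSI samples")
  check_refs(refs)
  structure(list(
    t_min = min(values), t_max = max(values), t_mean = mean(values),
    t_sd = stats::sd(values),
    cwsi_min = min(cwsi_values), cwsi_max = max(cwsi_values),
    cwsi_mean = mean(cwsi_values), cwsi_sd = stats::sd(cwsi_values),
    t_wet = refs$t_wet, t_dry = refs$t_dry,
    n_samples = length(values), spacing_cm = spacing,
    outlier_fraction = cwsi_outlier_fraction(cwsi_values)),
    class = "thermal_summary")
}

#' @export
print.thermal_summary <- function(x, ...) {
  cat(sprintf("<thermal_summary> n = %d (spacing %.3g cm)\n", x$n_samples,
              x$spacing_cm))
  cat(sprintf("  temp degC: min %.1f max %.1f mean %.1f sd %.2f\n",
              x$t_min, x$t_max, x$t_mean, x$t_sd))
  cat(sprintf("  CWSI: min %.2f max %.2f mean %.2f sd %.2f (%.2f%% outside [0,1])\n",
              x$cwsi_min, x$cwsi_max, x$cwsi_mean, x$cwsi_sd,
              100 * x$outlier_fraction))
  cat(sprintf("  references: t_wet %.1f t_dry %.1f\n", x$t_wet, x$t_dry))
  invisible(x)
}

#' @export
as.data.frame.thermal_summary <- function(x, ...) {
  data.frame(t_min = x$t_min, t_max = x$t_max, t_mean = x$t_mean,
             t_sd = x$t_sd, cwsi_min = x$cwsi_min, cwsi_max = x$cwsi_max,
             cwsi_mean = x$cwsi_mean, cwsi_sd = x$cwsi_sd, t_wet = x$t_wet,
             t_dry = x$t_dry, n_samples = x$n_samples,
             spacing_cm = x$spacing_cm,
             outlier_fraction = x$outlier_fraction)
}
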