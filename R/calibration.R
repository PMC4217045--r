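#' Fiber-optic ferrule geometry
#'
#' Describes the implanted optical fiber through which LED light is delivered.
#' Irradiance (mW/mm^2) is computed by dividing the emitted power by the core
#' cross-sectional area, so the core diameter is the geometric quantity that
#' converts a power-meter reading into a stimulation dose.
#'
#' @param core_diameter_um Fiber core diameter in micrometers (> 0).
#' @param numerical_aperture Fiber NA, strictly between 0 and 1.
#' @param wavelength_nm Nominal source wavelength in nanometers.
#' @return An object of class `fiber_spec`.
#' @examples
#' fiber_spec(200, 0.37, 465)
#' @export
fiber_spec <- function(core_diameter_um = 200, numerical_aperture = 0.37,
                       wavelength_nm = 465) {
  if (!is.numeric(core_diameter_um) || core_diameter_um <= 0)
    op_stop("fiber core diameter must be > 0 um", "optephys_config_error")
  if (numerical_aperture <= 0 || numerical_aperture >= 1)
    op_stop("numerical aperture must be in (0, 1)", "optephys_config_error")
  structure(list(core_diameter_um = as.numeric(core_diameter_um),
                 numerical_aperture = as.numeric(numerical_aperture),
                 wavelength_nm = as.numeric(wavelength_nm)),
            class = "fiber_spec")
}

#' LED driver voltage-to-current specification
#'
#' The LED controller converts an analog command voltage to drive current by a
#' linear, monotone map over its input range (default 0--5 V commanding
#' 0--300 mA).
#'
#' @param v_range Two-element numeric, command voltage range in volts.
#' @param i_range Two-element numeric, output current range in milliamps.
#' @return An object of class `driver_spec`.
#' @export
driver_spec <- function(v_range = c(0, 5), i_range = c(0, 300)) {
  if (length(v_range) != 2 || diff(v_range) <= 0)
    op_stop("v_range must be increasing", "optephys_config_error")
  if (length(i_range) != 2)
    op_stop("i_range must have two elements", "optephys_config_error")
  structure(list(v_range = as.numeric(v_range), i_range = as.numeric(i_range)),
            class = "driver_spec")
}

#' Drive current commanded by a voltage
#'
#' Affine interpolation of the driver's current range over its voltage range.
#'
#' @param v Command voltage(s), volts.
#' @param driver A [driver_spec()].
#' @param clip If `TRUE`, voltages outside the range are clipped to it;
#'   otherwise an out-of-range voltage is an error.
#' @return Current in milliamps, same length as `v`.
#' @examples
#' current_from_voltage(2.5, driver_spec())  # 150 mA
#' @export
current_from_voltage <- function(v, driver = driver_spec(), clip = FALSE) {
  stopifnot(inherits(driver, "driver_spec"))
  if (any(v < driver$v_range[1] | v > driver$v_range[2])) {
    if (!clip)
      op_stop("command voltage outside driver range", "optephys_range_error")
    v <- pmin(pmax(v, driver$v_range[1]), driver$v_range[2])
  }
  driver$i_range[1] + (v - driver$v_range[1]) / diff(driver$v_range) *
    diff(driver$i_range)
}

#' Convert emitted power to irradiance at the fiber tip
#'
#' Divides power by the core cross-sectional area pi * (d/2)^2.
#'
#' @param power_mw Measured power(s), milliwatts (>= 0).
#' @param fiber A [fiber_spec()].
#' @return Irradiance in mW/mm^2.
#' @examples
#' irradiance_from_power(1.5708, fiber_spec(200))  # ~50 mW/mm^2
#' @export
irradiance_from_power <- function(power_mw, fiber = fiber_spec()) {
  stopifnot(inherits(fiber, "fiber_spec"))
  if (any(power_mw < 0))
    op_stop("power must be >= 0", "optephys_parameter_error")
  d_mm <- fiber$core_diameter_um / 1000
  power_mw / (pi * (d_mm / 2)^2)
}

#' Fit a per-ferrule voltage-to-irradiance calibration curve
#'
#' Each implanted ferrule transmits a different fraction of the LED output, so
#' stimulation doses are standardized per ferrule: measured powers at a set of
#' command voltages are converted to irradiance and regressed (ordinary least
#' squares) on voltage. The fitted line, its voltage support and r^2 form the
#' calibration artifact used by the pattern generator.
#'
#' The intercept is estimated rather than forced through zero; real LEDs have
#' a turn-on offset and an anomalous intercept is a useful diagnostic. A
#' negative fitted slope does not error but sets `slope_warning` on the curve.
#'
#' @param points Data frame with columns `voltage_v` and `power_mw`, or a list
#'   of such pairs. At least 3 points spanning a nonzero voltage range.
#' @param fiber A [fiber_spec()].
#' @param safety_ceiling Maximum permitted predicted irradiance at `v_max`,
#'   mW/mm^2. The default 80 reflects the upper end of the non-damaging
#'   stimulation window for chronic optical stimulation.
#' @return An object of class `calibration_curve` with fields `slope`
#'   ((mW/mm^2)/V), `intercept` (mW/mm^2), `v_min`, `v_max`, `r_squared`,
#'   `fiber`, `slope_warning`.
#' @examples
#' pts <- data.frame(voltage_v = 0:5, power_mw = 0.0314159 * (0:5))
#' fit_calibration(pts, fiber_spec(200))
#' @export
fit_calibration <- function(points, fiber = fiber_spec(), safety_ceiling = 80) {
  points <- as.data.frame(points)
  if (!all(c("voltage_v", "power_mw") %in% names(points)))
    op_stop("calibration table needs columns voltage_v, power_mw",
            "optephys_config_error")
  points <- points[complete.cases(points[, c("voltage_v", "power_mw")]), ]
  if (nrow(points) < 3)
    op_stop("need at least 3 calibration points", "optephys_degenerate_fit_error")
  v <- points$voltage_v
  if (diff(range(v)) == 0)
    op_stop("all calibration voltages identical: cannot fit a line",
            "optephys_degenerate_fit_error")
  irr <- irradiance_from_power(points$power_mw, fiber)
  fit <- lm(irr ~ v)
  cf <- coef(fit)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((irr - mean(irr))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  v_max <- max(v)
  pred_max <- intercept + slope * v_max
  if (pred_max > safety_ceiling)
    op_stop(sprintf(
      "predicted irradiance at v_max (%.1f mW/mm^2) exceeds safety ceiling (%g)",
      pred_max, safety_ceiling), "optephys_safety_error")
  curve <- structure(list(slope = slope, intercept = intercept,
                          v_min = min(v), v_max = v_max,
                          r_squared = r2, fiber = fiber,
                          slope_warning = slope <= 0),
                     class = "calibration_curve")
  if (curve$slope_warning)
    warning("fitted calibration slope is not positive; curve flagged")
  curve
}

#' Predicted irradiance at a command voltage
#'
#' @param v Voltage(s) within the calibrated range.
#' @param curve A [fit_calibration()] result.
#' @param extrapolate Allow voltages outside `[v_min, v_max]`.
#' @return Irradiance in mW/mm^2.
#' @export
irradiance_at_voltage <- function(v, curve, extrapolate = FALSE) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!extrapolate && any(v < curve$v_min - 1e-12 | v > curve$v_max + 1e-12))
    op_stop("voltage outside calibrated range", "optephys_range_error")
  curve$intercept + curve$slope * v
}

#' Command voltage delivering a target irradiance
#'
#' Inverts the fitted calibration line. Targets above the calibrated maximum
#' are refused rather than extrapolated: over-driving the LED risks tissue
#' heating, so the calibrated range is treated as a hard safety envelope.
#'
#' @param target_irradiance Target dose(s), mW/mm^2.
#' @param curve A [fit_calibration()] result with positive slope.
#' @return Voltage(s) in volts.
#' @examples
#' pts <- data.frame(voltage_v = 0:5, power_mw = 0.0314159 * (0:5))
#' cc <- fit_calibration(pts)
#' voltage_for_irradiance(5, cc)
#' @export
voltage_for_irradiance <- function(target_irradiance, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0)
    op_stop("calibration slope not positive: cannot invert", "optephys_config_error")
  lo <- irradiance_at_voltage(curve$v_min, curve)
  hi <- irradiance_at_voltage(curve$v_max, curve)
  if (any(target_irradiance > hi + 1e-9))
    op_stop("target irradiance above calibrated maximum (refusing to extrapolate)",
            "optephys_range_error")
  if (any(target_irradiance < lo - 1e-9))
    op_stop("target irradiance below calibrated minimum", "optephys_range_error")
  (target_irradiance - curve$intercept) / curve$slope
}

#' Read a calibration CSV (columns `voltage_v,power_mw`)
#' @param path File path.
#' @return Data frame suitable for [fit_calibration()].
#' @export
read_calibration_points <- function(path) {
  pts <- read.csv(path)
  if (!all(c("voltage_v", "power_mw") %in% names(pts)))
    op_stop("calibration CSV must have header voltage_v,power_mw",
            "optephys_config_error")
  pts
}

#' Write / read a calibration curve as a JSON artifact
#' @param curve A `calibration_curve`.
#' @param path Output path.
#' @return `path`, invisibly (`write_calibration`); a `calibration_curve`
#'   (`read_calibration`).
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  out <- curve
  class(out) <- NULL
  out$fiber <- unclass(out$fiber)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fib <- fiber_spec(x$fiber$core_diameter_um, x$fiber$numerical_aperture,
                    x$fiber$wavelength_nm)
  structure(list(slope = x$slope, intercept = x$intercept, v_min = x$v_min,
                 v_max = x$v_max, r_squared = x$r_squared, fiber = fib,
                 slope_warning = isTRUE(x$slope_warning)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> irradiance = %.4g + %.4g * V  (mW/mm^2), V in [%.3g, %.3g], r^2 = %.5f\n",
    x$intercept, x$slope, x$v_min, x$v_max, x$r_squared))
  cat(sprintf("  fiber: %g um core, NA %.2f, %g nm\n",
              x$fiber$core_diameter_um, x$fiber$numerical_aperture,
              x$fiber$wavelength_nm))
  invisible(x)
}
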