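#' Describe a microscope objective
#'
#' Bundles the optical parameters of one objective from which the projected
#' DMD pixel size, field of view and depth of focus derive.
#'
#' @param name Objective label, e.g. `"20x air"`.
#' @param magnification Nominal magnification (> 0).
#' @param na Numerical aperture (> 0).
#' @param immersion_index Refractive index of the immersion medium
#'   (1.0 for air, 1.515 for oil); must be >= 1.
#' @param measured_pixel_size_um Optional measured size of one projected DMD
#'   pixel at this objective, in micrometres. When absent, the pixel size is
#'   scaled from a reference objective by the magnification ratio
#'   (see [pixel_size()]).
#' @return An object of class `"objective"`.
#' @seealso [pixel_size()], [depth_of_focus()], [optics_report()]
#' @export
#' @examples
#' objective("20x air", magnification = 20, na = 0.75)
objective <- function(name, magnification, na, immersion_index = 1,
                      measured_pixel_size_um = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(magnification) || magnification <= 0)
    stop("`magnification` must be > 0", call. = FALSE)
  if (!is.numeric(na) || na <= 0)
    stop("`na` must be > 0", call. = FALSE)
  if (!is.numeric(immersion_index) || immersion_index < 1)
    stop("`immersion_index` must be >= 1", call. = FALSE)
  if (!is.null(measured_pixel_size_um) && measured_pixel_size_um <= 0)
    stop("`measured_pixel_size_um` must be > 0 when given", call. = FALSE)
  structure(
    list(name = name, magnification = magnification, na = na,
         immersion_index = immersion_index,
         measured_pixel_size_um = measured_pixel_size_um),
    class = "objective")
}

#' @export
print.objective <- function(x, ...) {
  px <- if (is.null(x$measured_pixel_size_um)) "derived"
        else sprintf("%.3f um (measured)", x$measured_pixel_size_um)
  cat(sprintf("<objective> %s: %gx, NA %.2f, n %.3f, DMD pixel %s\n",
              x$name, x$magnification, x$na, x$immersion_index, px))
  invisible(x)
}

#' DMD resolution
#'
#' @param rows,cols Mirror counts of the digital micromirror device (> 0).
#' @return An object of class `"dmd_spec"`.
#' @export
#' @examples
#' dmd_spec(600, 800)  # Andor Mosaic 3
dmd_spec <- function(rows, cols) {
  if (rows <= 0 || cols <= 0) stop("DMD dimensions must be > 0", call. = FALSE)
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "dmd_spec")
}

#' Describe the exposure light source
#'
#' @param max_power_mW Optical power at the 100% LED setting, mW (>= 0).
#' @param wavelength_um Exposure wavelength in micrometres (> 0), e.g. 0.395
#'   for a 395 nm UV LED.
#' @param dmd_slope_mW_per_unit_fraction,dmd_intercept_mW Optional affine
#'   model of delivered power versus the fraction of DMD pixels switched ON
#'   (slope in mW per unit ON fraction, intercept in mW), as obtained from a
#'   power-meter calibration series.
#' @return An object of class `"light_source"`.
#' @export
light_source <- function(max_power_mW, wavelength_um,
                         dmd_slope_mW_per_unit_fraction = NULL,
                         dmd_intercept_mW = NULL) {
  if (max_power_mW < 0) stop("`max_power_mW` must be >= 0", call. = FALSE)
  if (wavelength_um <= 0) stop("`wavelength_um` must be > 0", call. = FALSE)
  structure(
    list(max_power_mW = max_power_mW, wavelength_um = wavelength_um,
         dmd_slope_mW_per_unit_fraction = dmd_slope_mW_per_unit_fraction,
         dmd_intercept_mW = dmd_intercept_mW),
    class = "light_source")
}

#' A fully specified exposure
#'
#' @param power_mW Delivered optical power, mW (>= 0).
#' @param time_ms Exposure duration, ms (>= 0).
#' @param area_mm2 Illuminated area, mm^2 (>= 0).
#' @return An object of class `"exposure_spec"` with the derived energy (mJ)
#'   and dose (mJ/mm^2) attached.
#' @export
exposure_spec <- function(power_mW, time_ms, area_mm2) {
  if (power_mW < 0 || time_ms < 0 || area_mm2 < 0)
    stop("exposure fields must be >= 0", call. = FALSE)
  e <- exposure_energy(power_mW, time_ms)
  structure(
    list(power_mW = power_mW, time_ms = time_ms, area_mm2 = area_mm2,
         energy_mJ = e,
         dose_mJ_mm2 = if (area_mm2 > 0) energy_dose(e, area_mm2) else NA_real_),
    class = "exposure_spec")
}

#' Projected DMD pixel size from a measured field width
#'
#' The practical resolution of the projection: the measured field-of-view
#' width divided by the DMD column count.
#'
#' @param fov_width_um Measured projection width, micrometres (> 0).
#' @param dmd_cols Number of DMD columns across that width (> 0).
#' @return Pixel size in micrometres per DMD pixel.
#' @export
#' @examples
#' dmd_pixel_size(560, 800)  # 0.7 um/px at a 20x objective
dmd_pixel_size <- function(fov_width_um, dmd_cols) {
  if (any(fov_width_um <= 0) || any(dmd_cols <= 0))
    stop("inputs must be > 0", call. = FALSE)
  fov_width_um / dmd_cols
}

#' Scale a pixel size between objectives
#'
#' The projected pixel size is inversely proportional to magnification, so a
#' pixel size measured at one objective transfers to another by the
#' magnification ratio.
#'
#' @param reference_px_um Pixel size at the reference objective, um (> 0).
#' @param reference_mag,target_mag Magnifications of the reference and target
#'   objectives (> 0).
#' @return Pixel size at the target objective, micrometres.
#' @export
#' @examples
#' scale_pixel_size(0.702, 20, 4)  # 3.51 um at 4x
scale_pixel_size <- function(reference_px_um, reference_mag, target_mag) {
  if (any(reference_px_um <= 0) || any(reference_mag <= 0) ||
      any(target_mag <= 0))
    stop("inputs must be > 0", call. = FALSE)
  reference_px_um * reference_mag / target_mag
}

#' Projected DMD pixel size for an objective
#'
#' Prefers the objective's own `measured_pixel_size_um`; otherwise scales the
#' reference objective's measured pixel size by the magnification ratio.
#'
#' @param obj An [objective()].
#' @param reference Reference [objective()] carrying a measured pixel size;
#'   defaults to the 20x reference at 0.702 um/px (421.2 um field height over
#'   600 DMD rows).
#' @return Pixel size in micrometres.
#' @export
pixel_size <- function(obj, reference = reference_objective()) {
  stopifnot(inherits(obj, "objective"))
  if (!is.null(obj$measured_pixel_size_um)) return(obj$measured_pixel_size_um)
  if (is.null(reference$measured_pixel_size_um))
    stop("reference objective has no measured pixel size", call. = FALSE)
  scale_pixel_size(reference$measured_pixel_size_um,
                   reference$magnification, obj$magnification)
}

#' The default 20x reference objective
#'
#' A 20x/0.75 air objective with a measured projected pixel size of
#' 0.702 um (421.2 um field height across 600 DMD rows).
#'
#' @return An [objective()].
#' @export
reference_objective <- function() {
  objective("20x air", magnification = 20, na = 0.75, immersion_index = 1,
            measured_pixel_size_um = 0.702)
}

#' Field-of-view dimensions of a DMD projection
#'
#' @param pixel_size_um Projected pixel size, um (> 0).
#' @param dmd A [dmd_spec()].
#' @return Named numeric `c(height_um, width_um)` =
#'   `(rows, cols) * pixel_size_um`.
#' @export
#' @examples
#' fov_dimensions(0.702, dmd_spec(600, 800))  # 421.2 x 561.6 um
fov_dimensions <- function(pixel_size_um, dmd) {
  stopifnot(inherits(dmd, "dmd_spec"))
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  c(height_um = dmd$rows * pixel_size_um, width_um = dmd$cols * pixel_size_um)
}

#' Depth of focus of an objective
#'
#' Standard scalar approximation `n * lambda / NA^2`: the axial range over
#' which the projected pattern stays acceptably sharp. High-NA objectives
#' give finer lateral resolution at the cost of a much shallower focus range.
#'
#' @param n Refractive index of the immersion medium (>= 1).
#' @param wavelength_um Exposure wavelength, micrometres (> 0).
#' @param na Numerical aperture (> 0).
#' @return Depth of focus in micrometres.
#' @export
#' @examples
#' depth_of_focus(1, 0.395, 0.13)      # 4x air: ~23.4 um
#' depth_of_focus(1.515, 0.395, 1.25)  # 100x oil: ~0.38 um
depth_of_focus <- function(n, wavelength_um, na) {
  if (any(na <= 0)) stop("`na` must be > 0", call. = FALSE)
  if (any(wavelength_um <= 0)) stop("`wavelength_um` must be > 0", call. = FALSE)
  if (any(n < 1)) stop("`n` must be >= 1", call. = FALSE)
  n * wavelength_um / na^2
}

#' LED output power at a fractional setting
#'
#' Assumes the optical output is linear in the LED power setting.
#'
#' @param fraction LED setting as a fraction in \[0, 1\].
#' @param source A [light_source()].
#' @return Power in mW.
#' @export
#' @examples
#' led_power(0.46, light_source(2.96, 0.395))  # ~1.36 mW
led_power <- function(fraction, source) {
  stopifnot(inherits(source, "light_source"))
  if (any(fraction < 0) || any(fraction > 1))
    stop("`fraction` must lie in [0, 1]", call. = FALSE)
  fraction * source$max_power_mW
}

#' Delivered power as a function of the DMD ON-pixel fraction
#'
#' Affine model `slope * on_fraction + intercept`, clamped at zero: the fit
#' is an approximation near zero and physical power cannot be negative.
#'
#' @param on_fraction Fraction of DMD pixels switched ON, in \[0, 1\].
#' @param source A [light_source()] carrying the affine slope and intercept.
#' @return Power in mW (>= 0).
#' @export
dmd_power <- function(on_fraction, source) {
  stopifnot(inherits(source, "light_source"))
  if (any(on_fraction < 0) || any(on_fraction > 1))
    stop("`on_fraction` must lie in [0, 1]", call. = FALSE)
  if (is.null(source$dmd_slope_mW_per_unit_fraction) ||
      is.null(source$dmd_intercept_mW))
    stop("light source has no DMD ON-fraction power model configured",
         call. = FALSE)
  pmax(0, source$dmd_slope_mW_per_unit_fraction * on_fraction +
          source$dmd_intercept_mW)
}

#' Exposure energy
#'
#' @param power_mW Delivered power, mW (>= 0).
#' @param time_ms Exposure time, ms (>= 0).
#' @return Energy in mJ (`power_mW * time_ms / 1000`).
#' @export
exposure_energy <- function(power_mW, time_ms) {
  if (any(power_mW < 0) || any(time_ms < 0))
    stop("inputs must be >= 0", call. = FALSE)
  power_mW * time_ms / 1000
}

#' Energy dose per unit area
#'
#' @param energy_mJ Delivered energy, mJ (>= 0).
#' @param area_mm2 Illuminated area, mm^2 (> 0).
#' @return Dose in mJ/mm^2. No intermediate rounding is applied.
#' @export
energy_dose <- function(energy_mJ, area_mm2) {
  if (any(area_mm2 <= 0)) stop("`area_mm2` must be > 0", call. = FALSE)
  if (any(energy_mJ < 0)) stop("`energy_mJ` must be >= 0", call. = FALSE)
  energy_mJ / area_mm2
}

#' Exposure time needed to reach a target dose
#'
#' Inverse of the energy/dose chain: the time such that
#' `energy_dose(exposure_energy(power_mW, time), area_mm2)` equals the target.
#'
#' @param target_dose_mJ_mm2 Target dose, mJ/mm^2 (>= 0).
#' @param power_mW Delivered power, mW (> 0).
#' @param area_mm2 Illuminated area, mm^2 (> 0).
#' @return Exposure time in ms.
#' @export
#' @examples
#' exposure_time_for_dose(0.5, 1.3616, 0.4212 * 0.5616)  # ~86.9 ms
exposure_time_for_dose <- function(target_dose_mJ_mm2, power_mW, area_mm2) {
  if (any(power_mW <= 0)) stop("`power_mW` must be > 0", call. = FALSE)
  if (any(area_mm2 <= 0)) stop("`area_mm2` must be > 0", call. = FALSE)
  if (any(target_dose_mJ_mm2 < 0))
    stop("`target_dose_mJ_mm2` must be >= 0", call. = FALSE)
  target_dose_mJ_mm2 * area_mm2 * 1000 / power_mW
}

#' Optical summary table for a set of objectives
#'
#' One row per objective: numerical aperture, projected DMD pixel size,
#' field-of-view dimensions and depth of focus at the source wavelength.
#'
#' @param objectives List of [objective()]s.
#' @param dmd A [dmd_spec()].
#' @param source A [light_source()] (supplies the wavelength).
#' @param reference Reference objective for pixel-size scaling.
#' @return A `data.frame` with columns `objective`, `magnification`, `na`,
#'   `immersion_index`, `pixel_size_um`, `fov_height_um`, `fov_width_um`,
#'   `depth_of_focus_um`.
#' @export
optics_report <- function(objectives, dmd, source,
                          reference = reference_objective()) {
  stopifnot(length(objectives) > 0)
  rows <- lapply(objectives, function(ob) {
    px <- pixel_size(ob, reference)
    fov <- fov_dimensions(px, dmd)
    data.frame(
      objective = ob$name, magnification = ob$magnification, na = ob$na,
      immersion_index = ob$immersion_index, pixel_size_um = px,
      fov_height_um = unname(fov["height_um"]),
      fov_width_um = unname(fov["width_um"]),
      depth_of_focus_um = depth_of_focus(ob$immersion_index,
                                         source$wavelength_um, ob$na),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
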