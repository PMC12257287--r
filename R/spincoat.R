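#' Spin-coat calibration curve
#'
#' Film thickness versus spin speed follows `h(RPM) = a / sqrt(RPM) + h0`:
#' thickness is inversely proportional to the square root of the spin speed,
#' with an optional constant offset that markedly improves the fit over a
#' wide RPM range.
#'
#' @param a Proportionality constant, um * RPM^(1/2) (> 0).
#' @param h0 Constant offset, micrometres.
#' @param r_squared Goodness of fit of the calibration, if known.
#' @return An object of class `"spin_curve"`.
#' @seealso [fit_spin_curve()], [predict_thickness()], [rpm_for_thickness()]
#' @export
spin_curve <- function(a, h0 = 0, r_squared = NA_real_) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be > 0", call. = FALSE)
  structure(list(a = a, h0 = h0, r_squared = r_squared),
            class = "spin_curve")
}

#' @export
print.spin_curve <- function(x, ...) {
  cat(sprintf("<spin_curve> h(RPM) = %.4g / sqrt(RPM) + %.4g um", x$a, x$h0))
  if (!is.na(x$r_squared)) cat(sprintf("  (R^2 = %.4f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Predict film thickness at a spin speed
#'
#' @param curve A [spin_curve()].
#' @param rpm Spin speed, revolutions per minute (> 0). Vectorised.
#' @return Predicted thickness in micrometres.
#' @export
#' @examples
#' predict_thickness(spin_curve(a = 481.23), 120)  # ~43.93 um
predict_thickness <- function(curve, rpm) {
  stopifnot(inherits(curve, "spin_curve"))
  if (any(rpm <= 0)) stop("`rpm` must be > 0", call. = FALSE)
  curve$a / sqrt(rpm) + curve$h0
}

#' Fit a spin-coat calibration curve
#'
#' Ordinary least squares of measured thickness against `1/sqrt(RPM)`: the
#' model is linear in `(a, h0)` after that substitution, so the fit is
#' closed-form with no iterative optimiser. With `with_offset = FALSE` the
#' intercept is forced to zero (`h = a / sqrt(RPM)`).
#'
#' @param points A data frame with columns `rpm` and `thickness_um`
#'   (both > 0), one calibration measurement per row.
#' @param with_offset Fit the constant offset `h0`? Default `TRUE`.
#' @return A [spin_curve()] with `r_squared` computed as
#'   `1 - SS_res / SS_tot`, `SS_tot` taken about the sample mean thickness.
#' @export
#' @examples
#' pts <- data.frame(rpm = c(200, 400, 800, 1600, 3200),
#'                   thickness_um = 1500 / sqrt(c(200, 400, 800, 1600, 3200)) + 8)
#' fit_spin_curve(pts)
fit_spin_curve <- function(points, with_offset = TRUE) {
  if (!is.data.frame(points) ||
      !all(c("rpm", "thickness_um") %in% names(points)))
    stop("`points` needs columns `rpm` and `thickness_um`", call. = FALSE)
  if (any(points$rpm <= 0) || any(points$thickness_um <= 0))
    stop("calibration points must be positive", call. = FALSE)
  n_min <- if (with_offset) 2L else 1L
  if (nrow(points) < n_min || length(unique(points$rpm)) < n_min)
    stop("need at least ", n_min, " distinct RPM values", call. = FALSE)
  d <- data.frame(h = points$thickness_um, x = 1 / sqrt(points$rpm))
  fit <- if (with_offset) stats::lm(h ~ x, data = d)
         else stats::lm(h ~ x + 0, data = d)
  cf <- stats::coef(fit)
  a <- unname(if (with_offset) cf["x"] else cf[1])
  h0 <- if (with_offset) unname(cf["(Intercept)"]) else 0
  if (!is.finite(a) || a <= 0)
    stop("degenerate calibration: fitted slope is not positive", call. = FALSE)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((d$h - mean(d$h))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  spin_curve(a = a, h0 = h0, r_squared = r2)
}

#' Spin speed needed for a target thickness
#'
#' Inverts the calibration curve: `RPM = (a / (h - h0))^2`.
#'
#' @param curve A [spin_curve()].
#' @param target_um Target thickness, micrometres; must exceed the curve's
#'   offset `h0` to be reachable.
#' @return Spin speed in RPM.
#' @export
rpm_for_thickness <- function(curve, target_um) {
  stopifnot(inherits(curve, "spin_curve"))
  if (any(target_um <= curve$h0))
    stop(sprintf(
      "target thickness %.3g um is unreachable: curve offset h0 = %.3g um",
      min(target_um), curve$h0), call. = FALSE)
  (curve$a / (target_um - curve$h0))^2
}

#' Layer constant of one thickness measurement
#'
#' Under the inverse-square-root law, `c = h * sqrt(RPM)` is constant across
#' spin speeds; comparing constants from independent prints checks whether
#' coating on glass and coating on a previously cured layer behave alike.
#'
#' @param thickness_um Measured film thickness, um (> 0).
#' @param rpm Spin speed used, RPM (> 0).
#' @return The layer constant, um * RPM^(1/2).
#' @export
#' @examples
#' layer_constant(43.93, 120)
layer_constant <- function(thickness_um, rpm) {
  if (any(thickness_um <= 0) || any(rpm <= 0))
    stop("inputs must be > 0", call. = FALSE)
  thickness_um * sqrt(rpm)
}

#' Multilayer stacking consistency error
#'
#' Symmetric relative difference of two layer constants, in percent:
#' `100 * |c1 - c2| / mean(c1, c2)`. Zero iff the constants agree; invariant
#' to rescaling both constants.
#'
#' @param c1,c2 Layer constants from [layer_constant()] (> 0).
#' @return Error in percent.
#' @export
#' @examples
#' multilayer_error(layer_constant(43.93, 120), layer_constant(34.885, 210))
multilayer_error <- function(c1, c2) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  if (any(c1 <= 0) || any(c2 <= 0))
    stop("layer constants must be > 0", call. = FALSE)
  100 * abs(c1 - c2) / ((c1 + c2) / 2)
}

#' Per-layer depth of a stacked print
#'
#' @param total_um Total measured depth of the stack, micrometres.
#' @param n_layers Number of stacked layers (>= 1).
#' @return Depth per layer in micrometres.
#' @export
#' @examples
#' split_stacked_depth(69.77, 2)  # 34.885 um per layer
split_stacked_depth <- function(total_um, n_layers) {
  if (any(n_layers < 1)) stop("`n_layers` must be >= 1", call. = FALSE)
  total_um / n_layers
}

#' Read a spin-coat calibration table
#'
#' @param path CSV file with a header row and columns `rpm,thickness_um`.
#' @return A data frame suitable for [fit_spin_curve()].
#' @export
read_spin_calibration <- function(path) {
  d <- utils::read.csv(path, header = TRUE)
  if (!all(c("rpm", "thickness_um") %in% names(d)))
    stop("calibration table must have header `rpm,thickness_um`",
         call. = FALSE)
  d[c("rpm", "thickness_um")]
}
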