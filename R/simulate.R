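clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Separable Gaussian blur with zero padding
#'
#' Convolves a matrix with a normalized Gaussian kernel (unit sum, radius
#' 4 sigma), applied separably along rows and columns. The image is treated
#' as zero outside its borders, so total intensity is conserved for
#' structures away from the edges.
#'
#' @param m Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels (>= 0; 0 returns `m` unchanged).
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(m, sigma_px) {
  if (!is.finite(sigma_px) || sigma_px < 0)
    stop("`sigma_px` must be finite and >= 0", call. = FALSE)
  if (sigma_px == 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  blur_1d <- function(x) {   # along rows of x (dimension 1), zero padded
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(nrow(x)) + off
      ok <- src >= 1 & src <= nrow(x)
      out[ok, ] <- out[ok, ] + k[i] * x[src[ok], , drop = FALSE]
    }
    out
  }
  t(blur_1d(t(blur_1d(m))))
}

new_dose_map <- function(grid, pixel_pitch_um, origin_um) {
  structure(list(grid = grid, pixel_pitch_um = pixel_pitch_um,
                 origin_um = origin_um),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d cells at %.3g um, dose %.4g-%.4g mJ/mm^2\n",
              nrow(x$grid), ncol(x$grid), x$pixel_pitch_um,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Simulate a print: accumulate UV dose on a virtual substrate
#'
#' Forward model of the projection lithography step. Each exposure of the
#' plan deposits `power_mW * time_ms / 1000 / FOV-area` (mJ/mm^2) uniformly
#' on every substrate cell whose center falls under an ON DMD pixel of its
#' (optionally jittered) field; the accumulated map is then convolved with a
#' Gaussian point-spread approximation. Deterministic for a given seed.
#'
#' @param plan A `"tile_plan"`.
#' @param power_mW Delivered optical power during each exposure, mW.
#' @param substrate_pitch_um Virtual substrate cell size, um; defaults to
#'   half the projected DMD pixel size (Nyquist with respect to the frame
#'   raster).
#' @param psf_sigma_um Gaussian blur sigma, um. Default 0 (ideal optics);
#'   [psf_sigma_default()] gives a diffraction-motivated value.
#' @param jitter_sd_um SD of independent Gaussian stage-position errors
#'   applied per exposure, um. Default 0.
#' @param seed Optional integer seed for the jitter draws.
#' @param margin_um Substrate margin beyond the union of fields, um.
#' @return A `"dose_map"`: accumulated dose grid (mJ/mm^2), cell pitch and
#'   stage coordinate of the grid's top-left corner.
#' @export
simulate_print <- function(plan, power_mW, substrate_pitch_um = NULL,
                           psf_sigma_um = 0, jitter_sd_um = 0, seed = NULL,
                           margin_um = NULL) {
  stopifnot(inherits(plan, "tile_plan"))
  if (!is.finite(power_mW) || power_mW < 0)
    stop("`power_mW` must be finite and >= 0", call. = FALSE)
  if (!is.finite(psf_sigma_um) || psf_sigma_um < 0 ||
      !is.finite(jitter_sd_um) || jitter_sd_um < 0)
    stop("sigma and jitter must be finite and >= 0", call. = FALSE)
  px <- plan$pixel_size_um
  if (is.null(substrate_pitch_um)) substrate_pitch_um <- px / 2
  if (substrate_pitch_um <= 0)
    stop("`substrate_pitch_um` must be > 0", call. = FALSE)
  if (is.null(margin_um)) margin_um <- 4 * psf_sigma_um + 3 * jitter_sd_um
  fov_w <- plan$dmd$cols * px
  fov_h <- plan$dmd$rows * px
  area_mm2 <- (fov_w / 1000) * (fov_h / 1000)

  if (!length(plan$exposures)) {
    return(new_dose_map(matrix(0, 1, 1), substrate_pitch_um, c(0, 0)))
  }
  ox <- vapply(plan$exposures, `[[`, 0, "origin_x_um")
  oy <- vapply(plan$exposures, `[[`, 0, "origin_y_um")
  x_min <- min(ox) - margin_um; x_max <- max(ox) + fov_w + margin_um
  y_min <- min(oy) - margin_um; y_max <- max(oy) + fov_h + margin_um
  nc <- max(1L, ceiling((x_max - x_min) / substrate_pitch_um))
  nr <- max(1L, ceiling((y_max - y_min) / substrate_pitch_um))
  grid <- matrix(0, nr, nc)
  xc <- x_min + (seq_len(nc) - 0.5) * substrate_pitch_um
  yc <- y_min + (seq_len(nr) - 0.5) * substrate_pitch_um

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  jx <- if (jitter_sd_um > 0)
    stats::rnorm(length(plan$exposures), 0, jitter_sd_um) else
    numeric(length(plan$exposures))
  jy <- if (jitter_sd_um > 0)
    stats::rnorm(length(plan$exposures), 0, jitter_sd_um) else
    numeric(length(plan$exposures))

  for (k in seq_along(plan$exposures)) {
    e <- plan$exposures[[k]]
    dose <- power_mW * e$time_ms / 1000 / area_mm2
    if (dose == 0) next
    x0 <- e$origin_x_um + jx[k]
    y0 <- e$origin_y_um + jy[k]
    ci <- floor((xc - x0) / px) + 1          # frame column per substrate col
    ri <- floor((yc - y0) / px) + 1
    cok <- which(ci >= 1 & ci <= plan$dmd$cols)
    rok <- which(ri >= 1 & ri <= plan$dmd$rows)
    if (!length(cok) || !length(rok)) next
    on <- e$frame[ri[rok], ci[cok], drop = FALSE]
    grid[rok, cok] <- grid[rok, cok] + dose * on
  }

  if (psf_sigma_um > 0)
    grid <- gaussian_blur(grid, psf_sigma_um / substrate_pitch_um)
  new_dose_map(grid, substrate_pitch_um, c(x_min, y_min))
}

#' Diffraction-motivated default PSF sigma
#'
#' Gaussian approximation of the diffraction-limited spot,
#' `0.21 * lambda / NA`. The practical printed resolution is usually coarser
#' (DMD mirror-edge artifacts), so this is a lower bound, exposed as a
#' configurable default rather than a claim.
#'
#' @param wavelength_um Exposure wavelength, um.
#' @param na Numerical aperture.
#' @return Sigma in micrometres.
#' @export
psf_sigma_default <- function(wavelength_um, na) {
  if (wavelength_um <= 0 || na <= 0) stop("inputs must be > 0", call. = FALSE)
  0.21 * wavelength_um / na
}

#' Threshold a dose map into a cured structure
#'
#' The resin hardens where the accumulated dose reaches the cure threshold;
#' unexposed regions stay soft and are washed away in development.
#'
#' @param dose A `"dose_map"`.
#' @param threshold_mJ_mm2 Cure threshold, mJ/mm^2 (> 0). Around
#'   0.5 mJ/mm^2 works well for consumer 3D-printing resin over a range of
#'   layer heights.
#' @return A `"cure_map"`: logical grid (TRUE = cured) plus pitch, origin
#'   and the threshold used.
#' @export
cure <- function(dose, threshold_mJ_mm2 = 0.5) {
  stopifnot(inherits(dose, "dose_map"))
  if (threshold_mJ_mm2 <= 0)
    stop("`threshold_mJ_mm2` must be > 0", call. = FALSE)
  structure(list(grid = dose$grid >= threshold_mJ_mm2,
                 pixel_pitch_um = dose$pixel_pitch_um,
                 origin_um = dose$origin_um,
                 threshold_mJ_mm2 = threshold_mJ_mm2),
            class = "cure_map")
}

#' @export
print.cure_map <- function(x, ...) {
  cat(sprintf("<cure_map> %d x %d cells at %.3g um, %.1f%% cured (>= %.3g mJ/mm^2)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_pitch_um,
              100 * mean(x$grid), x$threshold_mJ_mm2))
  invisible(x)
}

#' Cured area of a cure map
#'
#' @param cm A `"cure_map"`.
#' @return Cured area in um^2 (cured cell count times cell area).
#' @export
cured_area_um2 <- function(cm) {
  stopifnot(inherits(cm, "cure_map"))
  sum(cm$grid) * cm$pixel_pitch_um^2
}

#' Render a synthetic printed-grid micrograph with known ground truth
#'
#' Emulates a brightfield image of a printed line grid as used for stitching
#' quality control: dark horizontal and vertical lines on a bright
#' background, with per-line positional jitter, optional global rotation and
#' additive Gaussian pixel noise. The exact post-jitter line positions are
#' returned, so detection accuracy can be scored against truth.
#'
#' @param pitch_um Nominal line spacing, um; must exceed `line_width_um`.
#' @param n_lines Number of lines per axis (>= 2).
#' @param line_width_um Printed line width, um (> 0).
#' @param jitter_sd_um SD of independent Gaussian offsets added to each line
#'   position, um. Default 0.
#' @param angle_deg Rotation of the whole grid, degrees. Default 0.
#' @param noise_sd Additive Gaussian pixel noise SD, gray levels on a 0-1
#'   scale. Default 0.
#' @param pixel_size_um Image pixel size, um per px. Default 0.7.
#' @param seed Optional seed making jitter and noise reproducible.
#' @param margin_um Background margin around the grid. Default one pitch.
#' @return List with `image` (matrix in \[0, 1\], background 1, lines 0) and
#'   `truth`: nominal pitch, sorted jittered positions of vertical lines
#'   (`x_positions_um`) and horizontal lines (`y_positions_um`) in image
#'   coordinates before rotation, the realised jitter SD per axis, the
#'   rotation angle, and pixel size.
#' @export
synth_grid_image <- function(pitch_um, n_lines, line_width_um,
                             jitter_sd_um = 0, angle_deg = 0, noise_sd = 0,
                             pixel_size_um = 0.7, seed = NULL,
                             margin_um = pitch_um) {
  if (!(pitch_um > line_width_um && line_width_um > 0))
    stop("need pitch_um > line_width_um > 0", call. = FALSE)
  if (n_lines < 2) stop("`n_lines` must be >= 2", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  extent_um <- (n_lines - 1) * pitch_um + 2 * margin_um
  n_px <- ceiling(extent_um / pixel_size_um)
  nominal <- margin_um + (seq_len(n_lines) - 1) * pitch_um
  xpos <- sort(nominal + stats::rnorm(n_lines, 0, jitter_sd_um))
  ypos <- sort(nominal + stats::rnorm(n_lines, 0, jitter_sd_um))
  if (any(c(xpos, ypos) < line_width_um / 2) ||
      any(c(xpos, ypos) > extent_um - line_width_um / 2))
    stop("jittered lines exceed the image extent; increase `margin_um`",
         call. = FALSE)

  # pixel centers, rotated about the image center
  cc <- (seq_len(n_px) - 0.5) * pixel_size_um
  ctr <- extent_um / 2
  th <- angle_deg * pi / 180
  X <- matrix(rep(cc, each = n_px), n_px, n_px)   # x per column
  Y <- matrix(rep(cc, times = n_px), n_px, n_px)  # y per row
  U <- ctr + cos(th) * (X - ctr) + sin(th) * (Y - ctr)
  V <- ctr - sin(th) * (X - ctr) + cos(th) * (Y - ctr)

  dist_to <- function(coord, pos) {
    # distance from each value to the nearest line position
    i <- findInterval(coord, pos)
    lo <- pos[pmax(i, 1)]
    hi <- pos[pmin(i + 1, length(pos))]
    pmin(abs(coord - lo), abs(coord - hi))
  }
  dark <- dist_to(as.vector(U), xpos) <= line_width_um / 2 |
          dist_to(as.vector(V), ypos) <= line_width_um / 2
  img <- matrix(1, n_px, n_px)
  img[dark] <- 0
  if (noise_sd > 0)
    img <- clamp01(img + matrix(stats::rnorm(length(img), 0, noise_sd),
                                n_px, n_px))

  truth <- structure(list(
    pitch_um = pitch_um,
    x_positions_um = xpos, y_positions_um = ypos,
    jitter_sd_um = jitter_sd_um,
    realised_jitter_sd_um = c(x = stats::sd(xpos - nominal[order(nominal)]),
                              y = stats::sd(ypos - nominal[order(nominal)])),
    angle_deg = angle_deg, pixel_size_um = pixel_size_um,
    extent_um = extent_um), class = "synth_grid_truth")
  list(image = img, truth = truth)
}
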