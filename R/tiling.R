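#' A raster design in physical units
#'
#' Wraps a binary mask (TRUE / nonzero = expose) together with the physical
#' size of one design pixel and the stage coordinate of the design's top-left
#' corner. Coordinates follow raster order everywhere in the package: x
#' increases rightward (columns), y increases downward (rows), pixels are
#' half-open intervals.
#'
#' @param mask Logical or 0/1 matrix; rows are y, columns are x.
#' @param pixel_pitch_um Physical edge length of one design pixel, um (> 0).
#' @param origin_um Stage coordinate `c(x, y)` of the top-left corner.
#' @return An object of class `"design"`.
#' @export
design <- function(mask, pixel_pitch_um, origin_um = c(0, 0)) {
  if (!is.matrix(mask) || length(mask) == 0)
    stop("`mask` must be a non-empty matrix", call. = FALSE)
  if (pixel_pitch_um <= 0) stop("`pixel_pitch_um` must be > 0", call. = FALSE)
  mode(mask) <- "logical"
  structure(list(mask = mask, pixel_pitch_um = pixel_pitch_um,
                 origin_um = as.numeric(origin_um)),
            class = "design")
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf("<design> %d x %d px at %.3g um/px (%.4g x %.4g um), %d ON\n",
              nrow(x$mask), ncol(x$mask), x$pixel_pitch_um,
              nrow(x$mask) * x$pixel_pitch_um,
              ncol(x$mask) * x$pixel_pitch_um, sum(x$mask)))
  invisible(x)
}

#' Serpentine tile ordering
#'
#' Boustrophedon traversal of an `n_rows` x `n_cols` tile grid: row 1 left to
#' right, row 2 right to left, alternating. Consecutive tiles always differ
#' by one grid step, so total stage travel over the grid is minimal among
#' axis-aligned single-step traversals.
#'
#' @param n_rows,n_cols Tile counts (>= 0).
#' @return A data frame with columns `row` and `col` (1-based), one row per
#'   tile, in visit order.
#' @export
#' @examples
#' serpentine_order(2, 3)
serpentine_order <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 0 || n_cols < 0) stop("counts must be >= 0", call. = FALSE)
  if (n_rows == 0 || n_cols == 0)
    return(data.frame(row = integer(), col = integer()))
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- unlist(lapply(seq_len(n_rows), function(r) {
    if (r %% 2 == 1) seq_len(n_cols) else rev(seq_len(n_cols))
  }))
  data.frame(row = rows, col = cols)
}

new_tile_plan <- function(exposures, objective_name, dmd, pixel_size_um) {
  structure(list(exposures = exposures, objective_name = objective_name,
                 dmd = dmd, pixel_size_um = pixel_size_um),
            class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> %d exposures, %d x %d DMD, %.3g um/px (%s)\n",
              length(x$exposures), x$dmd$rows, x$dmd$cols, x$pixel_size_um,
              x$objective_name))
  invisible(x)
}

# DMD frame for one tile: a DMD pixel is ON iff its center falls inside an
# ON design pixel (nearest-neighbour; the DMD is binary so gray levels are
# meaningless). Tile origin in design-local um.
sample_frame <- function(mask, pitch, px, dmd, x0, y0) {
  xc <- x0 + (seq_len(dmd$cols) - 0.5) * px
  yc <- y0 + (seq_len(dmd$rows) - 0.5) * px
  ci <- floor(xc / pitch) + 1
  ri <- floor(yc / pitch) + 1
  frame <- matrix(FALSE, dmd$rows, dmd$cols)
  rok <- which(ri >= 1 & ri <= nrow(mask))
  cok <- which(ci >= 1 & ci <= ncol(mask))
  if (length(rok) && length(cok))
    frame[rok, cok] <- mask[ri[rok], ci[cok], drop = FALSE]
  frame
}

#' Decompose a design into an ordered sequence of DMD exposures
#'
#' Splits a physical-units design into abutting DMD fields of view, visited
#' in serpentine order, each with the stage coordinate of its field center
#' and its binary DMD frame (nearest-neighbour resampling of the mask).
#' Frames containing no ON pixel are dropped to save stage moves; the
#' skipped tiles are recorded in `attr(plan, "skipped")`.
#'
#' @param dsn A [design()].
#' @param obj The [objective()] used for projection.
#' @param dmd A [dmd_spec()].
#' @param time_ms Exposure duration applied to every frame, ms (>= 0).
#' @param overlap_um Optional tile overlap, um; overlapping ON pixels are
#'   simply exposed by both frames (logical OR on the substrate). Default 0
#'   (tiles abut exactly).
#' @param reference Reference objective for pixel-size scaling.
#' @return A `"tile_plan"`: ordered list of exposures, each with
#'   `stage_x_um`, `stage_y_um` (field center), `origin_x_um`, `origin_y_um`
#'   (field top-left), `tile_row`, `tile_col`, `frame`, `time_ms`.
#' @export
plan_tiles <- function(dsn, obj, dmd, time_ms, overlap_um = 0,
                       reference = reference_objective()) {
  stopifnot(inherits(dsn, "design"), inherits(dmd, "dmd_spec"))
  if (time_ms < 0) stop("`time_ms` must be >= 0", call. = FALSE)
  px <- pixel_size(obj, reference)
  fov_w <- dmd$cols * px
  fov_h <- dmd$rows * px
  if (overlap_um < 0 || overlap_um >= min(fov_w, fov_h))
    stop("`overlap_um` must lie in [0, min FOV extent)", call. = FALSE)
  W <- ncol(dsn$mask) * dsn$pixel_pitch_um
  H <- nrow(dsn$mask) * dsn$pixel_pitch_um
  stride_x <- fov_w - overlap_um
  stride_y <- fov_h - overlap_um
  n_x <- max(1L, as.integer(ceiling((W - overlap_um) / stride_x)))
  n_y <- max(1L, as.integer(ceiling((H - overlap_um) / stride_y)))
  order <- serpentine_order(n_y, n_x)
  exposures <- list()
  skipped <- integer(0)
  for (k in seq_len(nrow(order))) {
    i <- order$row[k]; j <- order$col[k]
    x0 <- (j - 1) * stride_x
    y0 <- (i - 1) * stride_y
    frame <- sample_frame(dsn$mask, dsn$pixel_pitch_um, px, dmd, x0, y0)
    if (!any(frame)) {
      skipped <- c(skipped, k)
      next
    }
    exposures[[length(exposures) + 1L]] <- list(
      stage_x_um = dsn$origin_um[1] + x0 + fov_w / 2,
      stage_y_um = dsn$origin_um[2] + y0 + fov_h / 2,
      origin_x_um = dsn$origin_um[1] + x0,
      origin_y_um = dsn$origin_um[2] + y0,
      tile_row = i, tile_col = j,
      frame = frame, time_ms = time_ms)
  }
  plan <- new_tile_plan(exposures, obj$name, dmd, px)
  attr(plan, "skipped") <- skipped
  attr(plan, "grid") <- c(n_rows = n_y, n_cols = n_x)
  plan
}

#' Rasterize a tile plan back onto a design grid
#'
#' Projects every ON DMD pixel of every exposure onto a design-pitch raster
#' (ignoring blur): the coverage oracle for tiling. When the design pitch
#' equals the projected DMD pitch and the extents divide evenly, this
#' reproduces the original mask exactly.
#'
#' @param plan A `"tile_plan"`.
#' @param dsn The [design()] providing the target grid.
#' @return A logical matrix with the dimensions of `dsn$mask`.
#' @export
rasterize_plan <- function(plan, dsn) {
  stopifnot(inherits(plan, "tile_plan"), inherits(dsn, "design"))
  out <- matrix(FALSE, nrow(dsn$mask), ncol(dsn$mask))
  px <- plan$pixel_size_um
  pitch <- dsn$pixel_pitch_um
  for (e in plan$exposures) {
    on <- which(e$frame, arr.ind = TRUE)
    if (!nrow(on)) next
    xc <- (e$origin_x_um - dsn$origin_um[1]) + (on[, 2] - 0.5) * px
    yc <- (e$origin_y_um - dsn$origin_um[2]) + (on[, 1] - 0.5) * px
    ci <- floor(xc / pitch) + 1
    ri <- floor(yc / pitch) + 1
    ok <- ri >= 1 & ri <= nrow(out) & ci >= 1 & ci <= ncol(out)
    out[cbind(ri[ok], ci[ok])] <- TRUE
  }
  out
}

#' Plan an exposure-time calibration series
#'
#' The easiest way to set the UV exposure time for a new resin / objective /
#' layer-height combination is an automated test series: the same frame
#' printed repeatedly along a row with increasing exposure times, inspected
#' after cleaning.
#'
#' @param base_frame Binary DMD frame to repeat.
#' @param times_ms Strictly increasing, non-negative exposure times, ms.
#' @param spacing_um Stage spacing between successive exposures, um.
#' @param pixel_size_um Projected DMD pixel size, um.
#' @param objective_name Label recorded in the plan.
#' @return A `"tile_plan"` with one exposure per time at
#'   `x = (i - 1) * spacing_um`, `y = 0` (field centers).
#' @export
plan_exposure_series <- function(base_frame, times_ms, spacing_um,
                                 pixel_size_um = 0.702,
                                 objective_name = "series") {
  if (!is.matrix(base_frame)) stop("`base_frame` must be a matrix", call. = FALSE)
  if (length(times_ms)) {
    if (any(times_ms < 0)) stop("times must be >= 0", call. = FALSE)
    if (length(times_ms) > 1 && any(diff(times_ms) <= 0))
      stop("times must be strictly increasing", call. = FALSE)
  }
  mode(base_frame) <- "logical"
  dmd <- dmd_spec(nrow(base_frame), ncol(base_frame))
  fov_w <- dmd$cols * pixel_size_um
  fov_h <- dmd$rows * pixel_size_um
  exposures <- lapply(seq_along(times_ms), function(i) {
    x <- (i - 1) * spacing_um
    list(stage_x_um = x, stage_y_um = 0,
         origin_x_um = x - fov_w / 2, origin_y_um = -fov_h / 2,
         tile_row = 1L, tile_col = i,
         frame = base_frame, time_ms = times_ms[i])
  })
  new_tile_plan(exposures, objective_name, dmd, pixel_size_um)
}

# Running 2-D window sums via an integral image; window h x w anchored at
# each valid top-left position.
window_sums <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  cs <- apply(m, 2, cumsum)               # cumulative down rows
  cs <- t(apply(cs, 1, cumsum))           # then across columns
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- cs
  ri <- seq_len(H - h + 1); ci <- seq_len(W - w + 1)
  S[ri + h, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + h, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

#' Locate a fiducial template in an image
#'
#' Normalized cross-correlation over all integer translations (FFT-based),
#' returning the translation of the best match relative to a reference
#' position, converted to micrometres. Used to register successive resin
#' layers on a printed fiducial marker.
#'
#' @param image Grayscale matrix (the camera field).
#' @param template Grayscale matrix, strictly smaller than `image` in both
#'   dimensions; must not be flat (zero variance).
#' @param pixel_size_um Camera pixel size, um per pixel.
#' @param ref_px Reference top-left position `c(row, col)` of the template;
#'   default centers the template in the image.
#' @param min_correlation Matches with peak correlation below this are
#'   flagged (`matched = FALSE`). Default 0.5.
#' @return List with `dx_um`, `dy_um` (x rightward, y downward),
#'   `correlation` (peak NCC in \[-1, 1\]) and `matched`.
#' @export
align_to_fiducial <- function(image, template, pixel_size_um,
                              ref_px = NULL, min_correlation = 0.5) {
  if (!is.matrix(image) || !is.matrix(template))
    stop("`image` and `template` must be matrices", call. = FALSE)
  if (nrow(template) >= nrow(image) || ncol(template) >= ncol(image))
    stop("`template` must be strictly smaller than `image`", call. = FALSE)
  if (stats::sd(template) == 0)
    stop("flat template: zero variance, cannot align", call. = FALSE)
  h <- nrow(template); w <- ncol(template)
  t0 <- template - mean(template)
  # cross-correlation of image with zero-mean template via FFT
  tp <- matrix(0, nrow(image), ncol(image))
  tp[seq_len(h), seq_len(w)] <- t0
  cc <- Re(stats::fft(stats::fft(image) * Conj(stats::fft(tp)),
                      inverse = TRUE)) / length(image)
  cc <- cc[seq_len(nrow(image) - h + 1), seq_len(ncol(image) - w + 1),
           drop = FALSE]
  s1 <- window_sums(image, h, w)
  s2 <- window_sums(image^2, h, w)
  denom <- sqrt(pmax(s2 - s1^2 / (h * w), 0) * sum(t0^2))
  ncc <- ifelse(denom > sqrt(.Machine$double.eps), cc / denom, 0)
  best <- arrayInd(which.max(ncc), dim(ncc))
  if (is.null(ref_px))
    ref_px <- floor((dim(image) - dim(template)) / 2) + 1
  list(dx_um = (best[2] - ref_px[2]) * pixel_size_um,
       dy_um = (best[1] - ref_px[1]) * pixel_size_um,
       correlation = max(ncc),
       matched = max(ncc) >= min_correlation)
}
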