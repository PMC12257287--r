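#' Bicubic image upscaling
#'
#' Separable Catmull-Rom interpolation by an integer factor, implemented as
#' two weight-matrix products. Edge samples are replicated.
#'
#' @param image Numeric matrix.
#' @param factor Integer upscale factor (>= 1).
#' @return Matrix with dimensions `dim(image) * factor`.
#' @export
upscale_bicubic <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1) return(image)
  weights <- function(n_in) {
    n_out <- n_in * factor
    W <- matrix(0, n_out, n_in)
    u <- (seq_len(n_out) - 0.5) / factor + 0.5   # in input sample index units
    k0 <- floor(u)
    t <- u - k0
    w <- cbind((-t + 2 * t^2 - t^3) / 2,
               (2 - 5 * t^2 + 3 * t^3) / 2,
               (t + 4 * t^2 - 3 * t^3) / 2,
               (-t^2 + t^3) / 2)
    for (j in 1:4) {
      k <- pmin(pmax(k0 + j - 2L, 1L), n_in)    # replicate edges
      W[cbind(seq_len(n_out), k)] <- W[cbind(seq_len(n_out), k)] + w[, j]
    }
    W
  }
  Wr <- weights(nrow(image))
  Wc <- weights(ncol(image))
  Wr %*% image %*% t(Wc)
}

#' Skeletonize a binary image
#'
#' Zhang-Suen morphological thinning to 1-px-wide curves.
#'
#' @param bw Logical (or 0/1) matrix.
#' @return Logical matrix of the same dimensions.
#' @export
skeletonize <- function(bw) {
  if (!is.matrix(bw)) stop("`bw` must be a matrix", call. = FALSE)
  mode(bw) <- "logical"
  .thin_zhang_suen(bw)
}

#' Preprocess a grid micrograph for line detection
#'
#' Upscales the image (bicubic), binarizes it with Otsu's threshold and
#' thins the result to a 1-px-wide skeleton — the input expected by
#' [detect_segments()].
#'
#' @param image Grayscale matrix with values in \[0, 1\].
#' @param upscale_factor Integer upscale factor (>= 1). Default 4.
#' @param dark_lines Are the printed lines darker than the background?
#'   Default `TRUE`.
#' @return Logical skeleton matrix, `dim(image) * upscale_factor`.
#' @export
qc_preprocess <- function(image, upscale_factor = 4, dark_lines = TRUE) {
  if (!is.matrix(image) || length(image) == 0)
    stop("`image` must be a non-empty matrix", call. = FALSE)
  if (stats::sd(image) == 0)
    stop("constant image: cannot threshold", call. = FALSE)
  up <- clamp01(upscale_bicubic(image, upscale_factor))
  thr <- EBImage::otsu(EBImage::Image(up))
  bw <- if (dark_lines) up < thr else up > thr
  skeletonize(bw)
}

#' Detect line segments with the probabilistic Hough transform
#'
#' Progressive probabilistic Hough line detection on a binary skeleton.
#' Randomly sampled skeleton pixels vote into a (rho, theta) accumulator;
#' once a bin passes `hough_threshold` votes the supporting pixel run is
#' traced (bridging gaps up to `max_gap_px`) and kept if at least
#' `min_length_px` long. Seeded for reproducibility.
#'
#' @param skeleton Logical matrix (output of [qc_preprocess()]).
#' @param hough_threshold Accumulator votes required, default 10.
#' @param min_length_px Minimum segment length in pixels; default 25% of the
#'   shorter image side.
#' @param max_gap_px Largest bridged gap along a line, default 5 px.
#' @param seed Optional integer seed.
#' @param theta_step_deg Angular resolution of the accumulator, default 1.
#' @return A data frame of segments: endpoints `x1,y1,x2,y2` (1-based pixel
#'   coordinates, x = column, y = row), `angle_deg` in (-90, 90] measured
#'   from the x axis, midpoint `mid_x,mid_y` and `length_px`.
#' @export
detect_segments <- function(skeleton, hough_threshold = 10,
                            min_length_px = NULL, max_gap_px = 5,
                            seed = NULL, theta_step_deg = 1) {
  if (!is.matrix(skeleton)) stop("`skeleton` must be a matrix", call. = FALSE)
  mode(skeleton) <- "logical"
  if (hough_threshold <= 0 || max_gap_px <= 0 || theta_step_deg <= 0)
    stop("parameters must be positive", call. = FALSE)
  if (is.null(min_length_px))
    min_length_px <- ceiling(0.25 * min(dim(skeleton)))
  if (min_length_px <= 0) stop("`min_length_px` must be positive", call. = FALSE)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  theta <- seq(-90, 90 - theta_step_deg, by = theta_step_deg) * pi / 180
  segs <- .hough_lines_prob(skeleton, as.integer(hough_threshold),
                            as.integer(min_length_px),
                            as.integer(max_gap_px), theta)
  segs <- as.data.frame(segs)
  if (!nrow(segs)) {
    return(data.frame(x1 = integer(), y1 = integer(), x2 = integer(),
                      y2 = integer(), angle_deg = numeric(),
                      mid_x = numeric(), mid_y = numeric(),
                      length_px = numeric()))
  }
  ang <- atan2(segs$y2 - segs$y1, segs$x2 - segs$x1) * 180 / pi
  ang <- ifelse(ang <= -90, ang + 180, ifelse(ang > 90, ang - 180, ang))
  segs$angle_deg <- ang
  segs$mid_x <- (segs$x1 + segs$x2) / 2
  segs$mid_y <- (segs$y1 + segs$y2) / 2
  segs$length_px <- sqrt((segs$x2 - segs$x1)^2 + (segs$y2 - segs$y1)^2)
  segs
}

# deviation of an angle in (-90, 90] from the nearest axis: horizontal
# segments report the angle itself, vertical ones the angle relative to 90
# degrees, both on a common (-45, 45] misalignment scale
axis_deviation <- function(angle_deg, axis) {
  if (axis == "horizontal") angle_deg
  else ifelse(angle_deg > 0, angle_deg - 90, angle_deg + 90)
}

# 1-D single-linkage grouping: a gap larger than tol starts a new group
chain_groups <- function(x, tol) {
  o <- order(x)
  breaks <- c(0, which(diff(x[o]) > tol), length(x))
  lapply(seq_len(length(breaks) - 1), function(i)
    o[(breaks[i] + 1):breaks[i + 1]])
}

merge_group <- function(segs, idx) {
  xs <- c(segs$x1[idx], segs$x2[idx])
  ys <- c(segs$y1[idx], segs$y2[idx])
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  best <- arrayInd(which.max(d), dim(d))
  p <- best[1]; q <- best[2]
  ang <- atan2(ys[q] - ys[p], xs[q] - xs[p]) * 180 / pi
  ang <- if (ang <= -90) ang + 180 else if (ang > 90) ang - 180 else ang
  data.frame(x1 = xs[p], y1 = ys[p], x2 = xs[q], y2 = ys[q],
             angle_deg = ang, n_segments = length(idx))
}

#' Group segments per physical bar and merge them
#'
#' Classifies segments as horizontal (|angle| <= 45 degrees) or vertical,
#' discards ones deviating more than `angle_tol_deg` from their axis, groups
#' the rest by the midpoint coordinate along the dominant axis (y for
#' horizontal bars, x for vertical) with 1-D single-linkage at `group_tol_px`,
#' and represents each group by the maximally distant pair among all pooled
#' endpoints — one merged line spanning the full extent of each physical bar.
#'
#' @param segments Data frame from [detect_segments()].
#' @param angle_tol_deg Largest accepted deviation from the assigned axis,
#'   degrees. Default 20.
#' @param group_tol_px Midpoint gaps larger than this start a new bar,
#'   pixels. Default 10 (half the expected pitch is a better choice when the
#'   pitch is known).
#' @return List with data frames `horizontal` and `vertical`; each row is a
#'   merged line with endpoints, `angle_deg`, `position_px` (midpoint
#'   coordinate along the dominant axis) and `n_segments`.
#' @export
group_and_merge <- function(segments, angle_tol_deg = 20, group_tol_px = 10) {
  if (angle_tol_deg <= 0 || group_tol_px <= 0)
    stop("tolerances must be > 0", call. = FALSE)
  empty <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), angle_deg = numeric(),
                      position_px = numeric(), n_segments = integer())
  out <- list(horizontal = empty, vertical = empty)
  if (!nrow(segments)) return(out)
  horiz <- abs(segments$angle_deg) <= 45
  for (axis in c("horizontal", "vertical")) {
    sel <- if (axis == "horizontal") horiz else !horiz
    sel <- sel & abs(axis_deviation(segments$angle_deg, axis)) <= angle_tol_deg
    if (!any(sel)) next
    segs <- segments[sel, , drop = FALSE]
    coord <- if (axis == "horizontal") segs$mid_y else segs$mid_x
    merged <- lapply(chain_groups(coord, group_tol_px),
                     function(idx) merge_group(segs, idx))
    merged <- do.call(rbind, merged)
    merged$position_px <- if (axis == "horizontal")
      (merged$y1 + merged$y2) / 2 else (merged$x1 + merged$x2) / 2
    out[[axis]] <- merged[order(merged$position_px), , drop = FALSE]
  }
  out
}

#' Orientation and pitch statistics of a detected grid
#'
#' Orientations are reported as deviation from the assigned axis, so both
#' axes share a common misalignment scale; pitch is the spacing between
#' midpoints of adjacent merged lines, converted to micrometres with the
#' known pixel size (corrected for the preprocessing upscale).
#'
#' @param horizontal,vertical Merged-line data frames from
#'   [group_and_merge()].
#' @param pixel_size_um Size of one original image pixel, um.
#' @param upscale_factor Upscale factor used in preprocessing.
#' @return A `"grid_qc_report"`: per axis, `n_lines`, `orientation_mean_deg`,
#'   `orientation_sd_deg`, `pitch_mean_um`, `pitch_sd_um` (pitch statistics
#'   are `NA` with fewer than 2 lines on the axis; SDs are `NA` with fewer
#'   than 2 values).
#' @export
grid_statistics <- function(horizontal, vertical, pixel_size_um,
                            upscale_factor = 1) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  scale <- pixel_size_um / upscale_factor
  one_axis <- function(m, axis) {
    dev <- axis_deviation(m$angle_deg, axis)
    pitches <- if (nrow(m) >= 2) diff(sort(m$position_px)) * scale else numeric()
    list(n_lines = nrow(m),
         orientation_mean_deg = if (nrow(m)) mean(dev) else NA_real_,
         orientation_sd_deg = if (nrow(m) >= 2) stats::sd(dev) else NA_real_,
         pitch_mean_um = if (length(pitches)) mean(pitches) else NA_real_,
         pitch_sd_um = if (length(pitches) >= 2) stats::sd(pitches) else NA_real_,
         pitches_um = pitches)
  }
  structure(list(horizontal = one_axis(horizontal, "horizontal"),
                 vertical = one_axis(vertical, "vertical"),
                 pixel_size_um = pixel_size_um,
                 upscale_factor = upscale_factor),
            class = "grid_qc_report")
}

#' @export
print.grid_qc_report <- function(x, ...) {
  cat("<grid_qc_report>\n")
  for (axis in c("horizontal", "vertical")) {
    a <- x[[axis]]
    cat(sprintf(
      "  %-10s n = %2d  orientation %6.3f +/- %s deg  pitch %s +/- %s um\n",
      axis, a$n_lines,
      a$orientation_mean_deg,
      ifelse(is.na(a$orientation_sd_deg), "NA",
             sprintf("%.3f", a$orientation_sd_deg)),
      ifelse(is.na(a$pitch_mean_um), "NA", sprintf("%.2f", a$pitch_mean_um)),
      ifelse(is.na(a$pitch_sd_um), "NA", sprintf("%.2f", a$pitch_sd_um))))
  }
  invisible(x)
}

#' End-to-end grid quality control
#'
#' Runs the full pipeline on a micrograph of a printed line grid:
#' preprocessing ([qc_preprocess()]), probabilistic Hough detection
#' ([detect_segments()]), per-bar merging ([group_and_merge()]) and
#' statistics ([grid_statistics()]).
#'
#' @param image Grayscale matrix in \[0, 1\].
#' @param pixel_size_um Physical size of one image pixel, um.
#' @param upscale_factor Preprocessing upscale factor, default 4.
#' @param expected_pitch_um Optional expected grid pitch; when given, the
#'   grouping tolerance defaults to half of it.
#' @param dark_lines Lines darker than background? Default `TRUE`.
#' @param hough_threshold,min_length_px,max_gap_px,theta_step_deg Passed to
#'   [detect_segments()] (in post-upscale pixels).
#' @param angle_tol_deg,group_tol_px Passed to [group_and_merge()];
#'   `group_tol_px` defaults to `expected_pitch_um / 2` (converted to
#'   post-upscale pixels) when an expected pitch is given, else 10 px.
#' @param seed Seed for the probabilistic detection, default 1.
#' @return A `"grid_qc_report"` (see [grid_statistics()]) with the merged
#'   lines attached as `attr(report, "lines")`.
#' @export
qc_grid <- function(image, pixel_size_um, upscale_factor = 4,
                    expected_pitch_um = NULL, dark_lines = TRUE,
                    hough_threshold = 10, min_length_px = NULL,
                    max_gap_px = 5, theta_step_deg = 1,
                    angle_tol_deg = 20, group_tol_px = NULL, seed = 1) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0", call. = FALSE)
  if (is.null(group_tol_px)) {
    group_tol_px <- if (!is.null(expected_pitch_um))
      expected_pitch_um / 2 * upscale_factor / pixel_size_um else 10
  }
  skel <- qc_preprocess(image, upscale_factor, dark_lines)
  segs <- detect_segments(skel, hough_threshold = hough_threshold,
                          min_length_px = min_length_px,
                          max_gap_px = max_gap_px, seed = seed,
                          theta_step_deg = theta_step_deg)
  lines <- group_and_merge(segs, angle_tol_deg = angle_tol_deg,
                           group_tol_px = group_tol_px)
  rep <- grid_statistics(lines$horizontal, lines$vertical,
                         pixel_size_um, upscale_factor)
  attr(rep, "lines") <- lines
  rep
}
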