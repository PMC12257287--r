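# QC fixtures are built by synth_grid_image with known ground truth;
# detection uses upscale 2 to keep the suite quick

test_that("preprocessing skeletonizes an ideal bar to its 1-px center line", {
  img <- matrix(1, 40, 60)
  img[, 28:32] <- 0  # 5-px-wide vertical dark bar
  sk <- qc_preprocess(img, upscale_factor = 1)
  expect_equal(dim(sk), dim(img))
  cols <- unique(which(sk, arr.ind = TRUE)[, 2])
  expect_length(cols, 1)
  expect_equal(cols, 30)
  # a single straight vertical curve (thinning trims a few end rows)
  expect_true(all(rowSums(sk) <= 1))
  expect_true(all(rowSums(sk[5:35, ]) == 1))
  expect_error(qc_preprocess(matrix(0.5, 10, 10)), "constant")
})

test_that("upscaling preserves dimensions times the factor", {
  img <- matrix(runif(30 * 20), 30, 20)
  expect_identical(upscale_bicubic(img, 1), img)
  up <- upscale_bicubic(img, 4)
  expect_equal(dim(up), c(120, 80))
  # smooth interpolation stays near the data range
  expect_lt(max(up), max(img) + 0.2)
  expect_gt(min(up), min(img) - 0.2)
})

test_that("skeleton length tracks true line geometry on a grid fixture", {
  g <- synth_grid_image(50, 6, 5, noise_sd = 0, pixel_size_um = 0.7, seed = 2)
  up <- 2
  sk <- qc_preprocess(g$image, up)
  extent_px <- ncol(g$image) * up
  # 6 + 6 lines spanning the image, minus shared crossings
  true_len <- 12 * extent_px - 36 * (5 / 0.7 * up)
  expect_lt(abs(sum(sk) - true_len) / true_len, 0.10)
})

test_that("segment detection finds straight lines at the right angle", {
  m <- matrix(FALSE, 200, 200)
  m[100, 10:190] <- TRUE
  segs <- detect_segments(m, hough_threshold = 10, min_length_px = 50,
                          max_gap_px = 5, seed = 1)
  expect_gte(nrow(segs), 1)
  expect_true(all(abs(segs$angle_deg) <= 1))
  expect_equal(nrow(detect_segments(matrix(FALSE, 50, 50), seed = 1)), 0)
  # deterministic given the seed
  g <- synth_grid_image(50, 5, 5, noise_sd = 0.02, seed = 4)
  sk <- qc_preprocess(g$image, 2)
  s1 <- detect_segments(sk, seed = 9)
  s2 <- detect_segments(sk, seed = 9)
  expect_identical(s1, s2)
})

test_that("grouping merges collinear halves and splits the two axes", {
  half <- data.frame(x1 = c(10, 60), y1 = c(50, 50),
                     x2 = c(45, 100), y2 = c(50, 50))
  half$angle_deg <- 0
  half$mid_x <- (half$x1 + half$x2) / 2
  half$mid_y <- 50
  half$length_px <- half$x2 - half$x1
  merged <- group_and_merge(half, group_tol_px = 10)
  expect_equal(nrow(merged$horizontal), 1)
  expect_equal(nrow(merged$vertical), 0)
  expect_equal(merged$horizontal$n_segments, 2L)
  expect_setequal(c(merged$horizontal$x1, merged$horizontal$x2), c(10, 100))

  both <- data.frame(x1 = c(0, 50), y1 = c(50, 0), x2 = c(100, 50),
                     y2 = c(50, 100), angle_deg = c(0, 90),
                     mid_x = c(50, 50), mid_y = c(50, 50),
                     length_px = c(100, 100))
  m2 <- group_and_merge(both, group_tol_px = 10)
  expect_equal(nrow(m2$horizontal), 1)
  expect_equal(nrow(m2$vertical), 1)
})

test_that("group count equals true line count at half-pitch tolerance", {
  g <- synth_grid_image(50, 10, 5, noise_sd = 0.02, pixel_size_um = 0.7,
                        seed = 3)
  up <- 2
  sk <- qc_preprocess(g$image, up)
  segs <- detect_segments(sk, seed = 1)
  merged <- group_and_merge(segs, group_tol_px = 25 * up / 0.7)
  expect_equal(nrow(merged$horizontal), 10)
  expect_equal(nrow(merged$vertical), 10)
})

test_that("grid statistics convert positions and report undefined pitch", {
  lines3 <- data.frame(x1 = 0, y1 = c(0, 100, 200), x2 = 500,
                       y2 = c(0, 100, 200), angle_deg = 0,
                       position_px = c(0, 100, 200), n_segments = 1L)
  vline <- data.frame(x1 = 50, y1 = 0, x2 = 50, y2 = 500, angle_deg = 90,
                      position_px = 50, n_segments = 1L)
  rep <- grid_statistics(lines3, vline, pixel_size_um = 0.5,
                         upscale_factor = 1)
  expect_equal(rep$horizontal$pitch_mean_um, 50)
  expect_equal(rep$horizontal$pitch_sd_um, 0)
  expect_equal(rep$horizontal$n_lines, 3)
  # single line: pitch undefined, orientation still reported
  expect_true(is.na(rep$vertical$pitch_mean_um))
  expect_equal(rep$vertical$orientation_mean_deg, 0)
  expect_error(grid_statistics(lines3, lines3, 0), "> 0")
})

test_that("end-to-end pitch on a noise-free grid is within a detection pixel", {
  g <- synth_grid_image(50, 10, 5, jitter_sd_um = 0, noise_sd = 0.02,
                        pixel_size_um = 0.7, seed = 3)
  rep <- qc_grid(g$image, 0.7, upscale_factor = 2, expected_pitch_um = 50,
                 seed = 1)
  for (axis in c("horizontal", "vertical")) {
    expect_equal(rep[[axis]]$n_lines, 10)
    expect_lt(abs(rep[[axis]]$pitch_mean_um - 50), 0.35)  # 1 detection px
    expect_lt(rep[[axis]]$orientation_sd_deg, 0.5)
    expect_lt(rep[[axis]]$pitch_sd_um, 0.5)  # sub-pixel consistency
  }
})

test_that("reported pitch scatter tracks injected jitter", {
  g <- synth_grid_image(50, 20, 5, jitter_sd_um = 2, noise_sd = 0.02,
                        pixel_size_um = 0.7, seed = 11)
  rep <- qc_grid(g$image, 0.7, upscale_factor = 2, expected_pitch_um = 50,
                 seed = 1)
  true_sd_x <- sd(diff(g$truth$x_positions_um))  # vertical lines
  true_sd_y <- sd(diff(g$truth$y_positions_um))  # horizontal lines
  expect_lt(abs(rep$vertical$pitch_sd_um - true_sd_x) / true_sd_x, 0.5)
  expect_lt(abs(rep$horizontal$pitch_sd_um - true_sd_y) / true_sd_y, 0.5)
  expect_lt(abs(rep$vertical$pitch_mean_um - mean(diff(g$truth$x_positions_um))), 1)
})

test_that("pipeline is transpose-invariant up to swapping the axes", {
  g <- synth_grid_image(50, 8, 5, jitter_sd_um = 1, noise_sd = 0.02,
                        pixel_size_um = 0.7, seed = 6)
  a <- qc_grid(g$image, 0.7, upscale_factor = 2, expected_pitch_um = 50,
               seed = 1)
  b <- qc_grid(t(g$image), 0.7, upscale_factor = 2, expected_pitch_um = 50,
               seed = 1)
  expect_equal(b$horizontal$n_lines, a$vertical$n_lines)
  expect_equal(b$vertical$n_lines, a$horizontal$n_lines)
  expect_equal(b$horizontal$pitch_mean_um, a$vertical$pitch_mean_um,
               tolerance = 0.01)
  expect_equal(b$vertical$pitch_mean_um, a$horizontal$pitch_mean_um,
               tolerance = 0.01)
})
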