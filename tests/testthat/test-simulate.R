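test_that("a single full-ON frame deposits the dosimetry-formula dose", {
  frame <- matrix(TRUE, 40, 50)
  plan <- plan_exposure_series(frame, 30, 600, pixel_size_um = 0.7)
  area_mm2 <- prod(dim(frame)) * 0.7^2 / 1e6
  expected <- energy_dose(exposure_energy(2, 30), area_mm2)
  dose <- simulate_print(plan, power_mW = 2, substrate_pitch_um = 0.35,
                         margin_um = 5)
  vals <- unique(round(as.vector(dose$grid), 9))
  expect_setequal(vals, round(c(0, expected), 9))
  # inside-FOV cells all carry the uniform dose
  inside <- dose$grid[dose$grid > 0]
  expect_equal(length(inside), prod(dim(frame)) * 4)
})

test_that("dose is additive over stacked exposures", {
  s <- small_setup()
  plan <- plan_tiles(s$dsn, s$obj, s$dmd, 30)
  plan2 <- plan
  plan2$exposures <- c(plan$exposures, plan$exposures)
  d1 <- simulate_print(plan, power_mW = 2, substrate_pitch_um = 0.35)
  d2 <- simulate_print(plan2, power_mW = 2, substrate_pitch_um = 0.35)
  expect_equal(d2$grid, 2 * d1$grid)
})

test_that("simulation is deterministic: same seed same map, no jitter any seed", {
  s <- small_setup()
  plan <- plan_tiles(s$dsn, s$obj, s$dmd, 30)
  a <- simulate_print(plan, 2, psf_sigma_um = 0.5, jitter_sd_um = 0, seed = 1)
  b <- simulate_print(plan, 2, psf_sigma_um = 0.5, jitter_sd_um = 0, seed = 2)
  expect_identical(a$grid, b$grid)
  c1 <- simulate_print(plan, 2, jitter_sd_um = 1, seed = 5)
  c2 <- simulate_print(plan, 2, jitter_sd_um = 1, seed = 5)
  c3 <- simulate_print(plan, 2, jitter_sd_um = 1, seed = 6)
  expect_identical(c1$grid, c2$grid)
  expect_false(identical(c1$grid, c3$grid))
})

test_that("Gaussian blur conserves total dose away from borders", {
  s <- small_setup()
  plan <- plan_tiles(s$dsn, s$obj, s$dmd, 30)
  sharp <- simulate_print(plan, 2, substrate_pitch_um = 0.35)
  blurred <- simulate_print(plan, 2, substrate_pitch_um = 0.35,
                            psf_sigma_um = 1)
  expect_equal(sum(blurred$grid) * blurred$pixel_pitch_um^2,
               sum(sharp$grid) * sharp$pixel_pitch_um^2,
               tolerance = 0.001)
})

test_that("blur kernel is normalized on plain matrices too", {
  m <- matrix(0, 61, 61); m[31, 31] <- 5
  b <- gaussian_blur(m, 3)
  expect_equal(sum(b), 5, tolerance = 1e-6)
  expect_equal(gaussian_blur(m, 0), m)
  expect_error(gaussian_blur(m, -1), ">= 0")
})

test_that("cure thresholds the dose map and is monotone in exposure time", {
  frame <- matrix(TRUE, 30, 30)
  mkdose <- function(t) {
    plan <- plan_exposure_series(frame, t, 100, pixel_size_um = 0.7)
    simulate_print(plan, power_mW = 0.05, substrate_pitch_um = 0.35,
                   psf_sigma_um = 2)
  }
  d <- mkdose(83)
  u <- max(d$grid)
  expect_equal(sum(cure(d, u * 1.01)$grid), 0)
  expect_gt(sum(cure(d, u * 0.5)$grid), 0)

  # cured area non-decreasing in exposure time at fixed threshold
  areas <- vapply(c(20, 40, 80, 160),
                  function(t) cured_area_um2(cure(mkdose(t), 0.3)), 0)
  expect_true(all(diff(areas) >= 0))

  # cured footprint shrinks as the threshold rises (blurred edges)
  areas_thr <- vapply(seq(0.2, 0.9, by = 0.1) * max(d$grid),
                      function(th) sum(cure(d, th)$grid), 0)
  expect_true(all(diff(areas_thr) <= 0))
})

test_that("end-to-end: cure of an unblurred print reproduces the design", {
  s <- small_setup()
  plan <- plan_tiles(s$dsn, s$obj, s$dmd, 30)
  dose <- simulate_print(plan, 2, substrate_pitch_um = 0.7)
  cm <- cure(dose, max(dose$grid) * 0.999)
  # the substrate spans whole tiles, so it may extend past the design;
  # the design region must match exactly and nothing outside may cure
  sub <- cm$grid[seq_len(nrow(s$dsn$mask)), seq_len(ncol(s$dsn$mask))]
  expect_identical(unname(sub), unname(s$dsn$mask))
  expect_equal(sum(cm$grid), sum(s$dsn$mask))
})

test_that("synthetic grids carry exact ground truth", {
  g <- synth_grid_image(50, 6, 5, jitter_sd_um = 0, noise_sd = 0, seed = 1)
  expect_true(all(abs(diff(g$truth$x_positions_um) - 50) < 1e-12))
  expect_true(all(abs(diff(g$truth$y_positions_um) - 50) < 1e-12))
  expect_equal(g$truth$angle_deg, 0)
  expect_true(all(g$image %in% c(0, 1)))

  gj <- synth_grid_image(50, 12, 5, jitter_sd_um = 2, seed = 7)
  offs <- gj$truth$x_positions_um - (50 + (0:11) * 50)
  expect_equal(unname(gj$truth$realised_jitter_sd_um["x"]), sd(offs))
  # deterministic given seed
  gj2 <- synth_grid_image(50, 12, 5, jitter_sd_um = 2, seed = 7)
  expect_identical(gj$image, gj2$image)

  expect_error(synth_grid_image(5, 6, 5, pixel_size_um = 0.7), "pitch")
  expect_error(synth_grid_image(50, 1, 5), ">= 2")
  expect_error(synth_grid_image(50, 6, 5, jitter_sd_um = 40, seed = 1,
                                margin_um = 1), "extent")
})
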