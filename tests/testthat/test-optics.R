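test_that("pixel size arithmetic matches measured projections", {
  expect_equal(dmd_pixel_size(560, 800), 0.7)
  expect_equal(dmd_pixel_size(800, 800), 1.0)
  expect_equal(dmd_pixel_size(421.2, 600), 0.702)
  expect_error(dmd_pixel_size(0, 800), "> 0")

  expect_equal(round(scale_pixel_size(0.702, 20, 4), 2), 3.51)
  expect_equal(scale_pixel_size(0.70, 20, 20), 0.70)
  expect_equal(round(scale_pixel_size(0.702, 20, 100), 2), 0.14)
  expect_error(scale_pixel_size(-1, 20, 4), "> 0")
})

test_that("pixel_size prefers a measured value and scales otherwise", {
  meas <- objective("20x", 20, 0.75, measured_pixel_size_um = 0.71)
  expect_equal(pixel_size(meas), 0.71)
  derived <- objective("4x", 4, 0.13)
  expect_equal(pixel_size(derived), 0.702 * 20 / 4)
})

test_that("field-of-view dimensions follow the DMD raster", {
  expect_equal(fov_dimensions(0.702, mosaic3()),
               c(height_um = 421.2, width_um = 561.6))
  expect_equal(fov_dimensions(1, mosaic3()),
               c(height_um = 600, width_um = 800))
  expect_equal(fov_dimensions(0.14, mosaic3()),
               c(height_um = 84, width_um = 112))
})

test_that("depth of focus reproduces the study objectives to 2 decimals", {
  expect_equal(round(depth_of_focus(1.0, 0.395, 0.13), 2), 23.37)
  expect_equal(round(depth_of_focus(1.0, 0.395, 0.75), 2), 0.70)
  expect_equal(round(depth_of_focus(1.0, 0.395, 0.95), 2), 0.44)
  expect_equal(round(depth_of_focus(1.515, 0.395, 1.25), 2), 0.38)
  expect_equal(depth_of_focus(1.0, 0.395, 1.0), 0.395)
  expect_error(depth_of_focus(1.0, 0.395, 0), "> 0")
})

test_that("depth of focus is decreasing in NA and linear in n and lambda", {
  nas <- seq(0.1, 1.4, by = 0.05)
  expect_true(all(diff(depth_of_focus(1, 0.395, nas)) < 0))
  ns <- seq(1, 1.6, by = 0.1)
  expect_equal(depth_of_focus(ns, 0.395, 0.75),
               ns * depth_of_focus(1, 0.395, 0.75))
  ls <- seq(0.2, 0.8, by = 0.1)
  expect_equal(depth_of_focus(1, ls, 0.75),
               ls / 0.395 * depth_of_focus(1, 0.395, 0.75))
})

test_that("LED power is linear in the setting and bounded to [0, 1]", {
  src <- uv_source()
  expect_equal(round(led_power(0.46, src), 2), 1.36)
  expect_equal(round(led_power(0.64, src), 2), 1.89)
  expect_equal(led_power(0, src), 0)
  expect_error(led_power(1.2, src), "\\[0, 1\\]")
})

test_that("DMD ON-fraction power model is affine, clamped, monotone", {
  src <- uv_source()
  expect_equal(dmd_power(1, src), 2.69)
  expect_equal(dmd_power(0, src), 0)
  expect_equal(dmd_power(0.5, src), 1.335)
  fr <- seq(0, 1, by = 0.01)
  p <- dmd_power(fr, src)
  expect_true(all(p >= 0))
  expect_true(all(diff(p) >= 0))
  no_model <- light_source(2.96, 0.395)
  expect_error(dmd_power(0.5, no_model), "model")
})

test_that("energy and dose chain reproduces the printed dosimetry", {
  src <- uv_source()
  area <- prod(fov_dimensions(0.702, mosaic3())) / 1e6
  expect_equal(round(area, 3), 0.237)
  e46 <- exposure_energy(led_power(0.46, src), 83)
  e64 <- exposure_energy(led_power(0.64, src), 83)
  expect_equal(round(e46, 3), 0.113)
  expect_equal(round(e64, 3), 0.157)
  expect_equal(exposure_energy(0, 83), 0)
  expect_equal(round(energy_dose(e46, area), 3), 0.478)
  expect_equal(round(energy_dose(e64, area), 3), 0.665)
  expect_equal(energy_dose(1, 1), 1)
  expect_error(energy_dose(1, 0), "> 0")
})

test_that("exposure_time_for_dose inverts the dose chain", {
  area <- prod(fov_dimensions(0.702, mosaic3())) / 1e6
  t83 <- exposure_time_for_dose(0.478, 1.3616, area)
  expect_lt(abs(t83 - 83), 0.5)
  expect_equal(exposure_time_for_dose(0, 2, 1), 0)
  t05 <- exposure_time_for_dose(0.5, 1.3616, area)
  expect_equal(round(t05, 1), 86.9)
  expect_error(exposure_time_for_dose(0.5, 0, 1), "> 0")

  # property: round trip is the identity to 1e-9 relative
  set.seed(42)
  for (i in 1:50) {
    p <- runif(1, 0.1, 10); a <- runif(1, 0.01, 5); t <- runif(1, 1, 1000)
    d <- energy_dose(exposure_energy(p, t), a)
    expect_equal(exposure_time_for_dose(d, p, a), t, tolerance = 1e-9)
  }
})

test_that("optics_report assembles the per-objective summary", {
  rep <- optics_report(study_objectives(), mosaic3(), uv_source())
  expect_equal(nrow(rep), 4)
  expect_equal(round(rep$pixel_size_um, 2), c(3.51, 0.70, 0.35, 0.14))
  expect_equal(round(rep$depth_of_focus_um, 2), c(23.37, 0.70, 0.44, 0.38))
})
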