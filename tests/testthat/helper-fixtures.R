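# shared fixtures built in code

uv_source <- function() light_source(2.96, 0.395, 2.71, -0.02)

study_objectives <- function() list(
  objective("4x air", 4, 0.13, 1),
  objective("20x air", 20, 0.75, 1, measured_pixel_size_um = 0.702),
  objective("40x air", 40, 0.95, 1),
  objective("100x oil", 100, 1.25, 1.515))

mosaic3 <- function() dmd_spec(600, 800)

# small random design on a small DMD so tiling tests stay fast
small_setup <- function(seed = 2, nrow_px = 100, ncol_px = 120,
                        fill = 0.3) {
  set.seed(seed)
  list(dmd = dmd_spec(40, 50),
       obj = objective("20x", 20, 0.75, 1, measured_pixel_size_um = 0.7),
       dsn = design(matrix(runif(nrow_px * ncol_px) < fill,
                           nrow_px, ncol_px), 0.7))
}

exact_spin_points <- function(a = 1500, h0 = 8,
                              rpm = c(200, 400, 800, 1600, 3200)) {
  data.frame(rpm = rpm, thickness_um = a / sqrt(rpm) + h0)
}
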