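test_that("USAF frequency arithmetic and bar widths", {
  expect_equal(round(usaf_frequency(0, 5), 2), 1.59)
  expect_equal(round(usaf_frequency(2, 3), 2), 5.04)
  expect_equal(usaf_frequency(1, 1), 2)
  expect_equal(usaf_frequency(0, 1), 1)
  expect_error(usaf_frequency(0, 7), "1..6")
  # doubles across groups at fixed element; monotone in element
  for (e in 1:6)
    expect_equal(usaf_frequency(1, e) / usaf_frequency(0, e), 2)
  f <- usaf_frequency(0, 1:6)
  expect_true(all(diff(f) > 0))
  expect_equal(feature_size(2), 0.25)
  expect_equal(round(feature_size(usaf_frequency(0, 5)), 2), 0.31)
  expect_equal(feature_size(1), 0.5)
})

test_that("pixel pitch comes out right from spans and from Ronchi images", {
  expect_equal(round(estimate_pixel_pitch(span_mm = 50, span_px = 401), 2), 0.12)
  expect_equal(round(estimate_pixel_pitch(span_mm = 38, span_px = 1173), 2), 0.03)

  # bar edges on pixel boundaries: sub-pixel interpolation is then exact
  pitch_true <- 0.1
  rc <- render_scene(scene_spec("ronchi", frequency_lpmm = 0.5, axis = "slit"),
                     c(6, 240), pitch_true)
  img <- rc$frac
  est <- estimate_pixel_pitch(img, 0.5, axis = "slit")
  expect_equal(est, pitch_true, tolerance = 1e-6)
  # invariant to intensity scaling and contrast inversion
  expect_equal(estimate_pixel_pitch(7 * img + 2, 0.5, axis = "slit"), est)
  expect_equal(estimate_pixel_pitch(max(img) - img, 0.5, axis = "slit"), est,
               tolerance = 1e-9)
  expect_error(estimate_pixel_pitch(img[, 1:20], 0.5, axis = "slit"),
               "periods")
})

test_that("resolving power finds the finest element the PSF leaves visible", {
  dm <- coarse_model()
  els <- data.frame(group = 0L, element = 1:6)
  sc <- scene_spec("usaf1951", elements = els)

  sharp <- quiet_config(n_slit = 90, n_spectral = 64, pitch_mm = 0.12,
                        speed_factor = 1)
  cube <- simulate_scan(sc, default_led_panel(), dm, sharp, n_lines = 170)
  rp <- resolving_power(cube, band = 32, axis = "slit",
                        elements = cube$ground_truth$usaf_elements)
  expect_true(rp$discernible)
  expect_equal(c(rp$group, rp$element), c(0, 6))   # finest rendered element

  # anisotropic PSF: wider along scan -> scan axis resolves less
  aniso <- quiet_config(n_slit = 90, n_spectral = 64, pitch_mm = 0.12,
                        speed_factor = 1, spatial_fwhm_px = c(slit = 1, scan = 5))
  cube2 <- simulate_scan(sc, default_led_panel(), dm, aniso, n_lines = 170)
  rp_slit <- resolving_power(cube2, 32, "slit",
                             cube2$ground_truth$usaf_elements)
  rp_scan <- resolving_power(cube2, 32, "scan",
                             cube2$ground_truth$usaf_elements)
  expect_true(rp_slit$frequency_lpmm > rp_scan$frequency_lpmm ||
                (!rp_scan$discernible && rp_slit$discernible))

  # heavy blur in both axes -> nothing discernible
  blurred <- quiet_config(n_slit = 90, n_spectral = 64, pitch_mm = 0.12,
                          speed_factor = 1, spatial_fwhm_px = c(14, 14))
  cube3 <- simulate_scan(sc, default_led_panel(), dm, blurred, n_lines = 170)
  rp3 <- resolving_power(cube3, 32, "slit", cube3$ground_truth$usaf_elements)
  expect_false(rp3$discernible)
  expect_true(is.na(rp3$group))
})

test_that("scan aspect measures elongation and its corrective factor", {
  dm <- coarse_model()
  sc <- scene_spec("square_grid", frequency_lpmm = 0.2)
  fast <- quiet_config(n_slit = 160, n_spectral = 16, pitch_mm = 0.12,
                       speed_factor = 1.06)
  g <- simulate_scan(sc, default_led_panel(), dispersion_model(400, 40, 0, 0, n_pixels = 16),
                     fast, n_lines = 170)
  asp <- scan_aspect(g, 5)
  expect_equal(asp$elongation_pct, 6, tolerance = 0.5)

  ok <- quiet_config(n_slit = 160, n_spectral = 16, pitch_mm = 0.12,
                     speed_factor = 1)
  g0 <- simulate_scan(sc, default_led_panel(), dispersion_model(400, 40, 0, 0, n_pixels = 16),
                      ok, n_lines = 170)
  asp0 <- scan_aspect(g0, 5)
  expect_lt(abs(asp0$elongation_pct), 0.5)

  # applying the corrective factor pushes elongation to about a pixel
  corr <- quiet_config(n_slit = 160, n_spectral = 16, pitch_mm = 0.12,
                       speed_factor = 1.06 * asp$speed_correction)
  g2 <- simulate_scan(sc, default_led_panel(), dispersion_model(400, 40, 0, 0, n_pixels = 16),
                      corr, n_lines = 170)
  asp2 <- scan_aspect(g2, 5)
  period_px <- asp$period_px[["slit"]]
  expect_lt(abs(asp2$elongation_pct) / 100 * period_px, 1)  # <= 1 px equivalent
})
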