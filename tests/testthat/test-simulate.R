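test_that("a degenerate config yields identical rows up to vignetting", {
  ins <- quiet_config(n_slit = 12, n_spectral = 128)
  dm <- dispersion_model(400, 600 / 127, 0, 0, n_pixels = 128)
  cube <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins,
                        n_lines = 2)
  frame <- cube$values[1, , ]
  descaled <- frame / ins$vignetting
  spread <- apply(descaled, 2, function(col) diff(range(col)))
  expect_lt(max(spread / pmax(colMeans(descaled), 1e-9)), 1e-9)
})

test_that("counts are linear in exposure and reproducible under a seed", {
  ins <- instrument_config(n_slit = 10, n_spectral = 64)
  dm <- dispersion_model(400, 600 / 63, 0, 0, n_pixels = 64)
  a <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins,
                     n_lines = 2, seed = 5)
  b <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins,
                     n_lines = 2, seed = 5)
  expect_identical(a$values, b$values)
  expect_identical(a$ground_truth$dispersion, unname(dm$coefficients))

  quiet <- quiet_config(n_slit = 10, n_spectral = 64)
  x1 <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, quiet,
                      n_lines = 1, exposure = 1)
  x3 <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, quiet,
                      n_lines = 1, exposure = 3)
  expect_equal(x3$values, 3 * x1$values, tolerance = 1e-12)
})

test_that("a monochromatic line lands at the dispersed pixel with the set width", {
  dm <- paper_model()
  ins <- quiet_config(n_slit = 8)
  lam0 <- 632.8
  cube <- simulate_scan(scene_spec("uniform"), monochromatic_spectrum(lam0),
                        dm, ins, n_lines = 1)
  spec <- colMeans(scan_average(cube))
  pk <- detect_peaks(spec, 0.5, 5)
  expect_equal(pk$centroid_px, pixel_of_wavelength(dm, lam0),
               tolerance = 0.05)
  fw <- measure_fwhm(spec, pk$centroid_px, dm)
  expect_equal(fw$fwhm_nm, ins$slit_fwhm_nm, tolerance = 0.05 * 2.9)  # +-5%
})

test_that("noiseless lamps give a near-exact calibration round trip", {
  dm <- paper_model()
  peaks <- four_lamp_peaks(dm)
  matches <- suppressMessages(assign_lines(peaks))
  fit <- fit_dispersion(matches)
  x <- seq(0, 2047, by = 20)
  err <- abs(wavelength_of_pixel(fit$model, x) - wavelength_of_pixel(dm, x))
  # centroids of overlapping Gaussian lines carry tiny tail-induced bias, so
  # "exact" here means far below a hundredth of a pixel in wavelength
  expect_lt(max(err), 0.05 * 0.306)
  expect_gte(fit$n_lines, 40)
})

test_that("the ground-truth record regenerates the identical cube", {
  ins <- instrument_config(n_slit = 10, n_spectral = 64, smile_px = 1,
                           keystone_px = 2, speed_factor = 1.03)
  dm <- dispersion_model(400, 600 / 63, 0, 0, n_pixels = 64)
  a <- simulate_scan(scene_spec("ronchi", frequency_lpmm = 0.5),
                     default_led_panel(), dm, ins, n_lines = 3, seed = 11,
                     t_min = 5)
  gt <- a$ground_truth
  ins2 <- instrument_config(n_slit = 10, n_spectral = 64,
                            smile_px = gt$smile_px,
                            keystone_px = gt$keystone_px,
                            speed_factor = gt$speed_factor)
  b <- simulate_scan(scene_spec("ronchi", frequency_lpmm = 0.5),
                     default_led_panel(),
                     dispersion_model(gt$dispersion[1], gt$dispersion[2],
                                      gt$dispersion[3], gt$dispersion[4],
                                      n_pixels = 64),
                     ins2, n_lines = 3, seed = gt$seed, t_min = gt$t_min)
  expect_identical(a$values, b$values)
})
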