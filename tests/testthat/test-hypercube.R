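test_that("hypercube constructor enforces its invariants", {
  v <- array(1, c(2, 3, 4))
  expect_s3_class(hypercube(v), "hypercube")
  expect_error(hypercube(matrix(1, 2, 2)), "3-D array")
  expect_error(hypercube(array(-1, c(1, 1, 1))), "non-negative")
  expect_error(hypercube(array(NA_real_, c(1, 1, 1))), "finite")
  expect_error(hypercube(v, wavelength = c(400, 410)), "length")
  expect_error(hypercube(v, wavelength = c(400, 410, 410, 420)),
               "strictly increasing")
})

test_that("white/dark normalization reproduces the algebraic identities", {
  d <- array(100, c(4, 5, 6))
  w <- array(900, c(4, 5, 6))
  dark <- hypercube(d); white <- hypercube(w)

  r1 <- normalize_cube(hypercube(w), white, dark)        # S = Wbar
  expect_true(all(abs(r1$values - 1) < 1e-12))
  r0 <- normalize_cube(hypercube(d), white, dark)        # S = Dbar
  expect_true(all(abs(r0$values) < 1e-12))
  rm_ <- normalize_cube(hypercube((d + w) / 2), white, dark)
  expect_true(all(abs(rm_$values - 0.5) < 1e-12))

  # dark is optional (treated as all-zero)
  rnd <- normalize_cube(hypercube(w / 2), white)
  expect_true(all(abs(rnd$values - 0.5) < 1e-12))
})

test_that("normalization clips specular outliers and flags bad denominators", {
  white <- hypercube(array(c(rep(1000, 6), rep(0, 6)), c(1, 2, 6)))
  dark <- hypercube(array(0, c(1, 2, 6)))
  raw <- hypercube(array(2000, c(1, 2, 6)))
  expect_warning(r <- normalize_cube(raw, white, dark, clip_max = 1.5),
                 "non-positive")
  expect_true(all(r$values <= 1.5))
  expect_true(all(r$mask[, 2, ]))        # zero-denominator slit column
  expect_true(all(r$mask[, 1, ]))        # clipped (2000/1000 = 2 > 1.5)
})

test_that("extract_band picks the nearest band with the documented tie rule", {
  v <- array(rep(1:3, each = 4), c(2, 2, 3))
  cube <- hypercube(v, wavelength = c(499.8, 500.1, 500.4))
  b <- extract_band(cube, 500)
  expect_equal(attr(b, "wavelength_nm"), 500.1)
  expect_equal(unname(b[1, 1]), 2)
  # exactly between two bands -> lower band
  cube2 <- hypercube(v, wavelength = c(400, 410, 425))
  expect_equal(attr(extract_band(cube2, 405), "wavelength_nm"), 400)
  expect_error(extract_band(cube, 350), "outside")
  expect_error(extract_band(hypercube(v), 500), "wavelength axis")
})

test_that("spatial binning averages slit groups and records the factor", {
  cube <- hypercube(array(c(1, 1, 3, 3, 5, 5, 7, 7), c(2, 4, 1)))
  expect_identical(bin_spatial(cube, 1), cube)
  b <- bin_spatial(cube, 2)
  expect_equal(dim(b), c(2, 2, 1))
  expect_equal(as.vector(b$values[1, , 1]), c(2, 6))
  expect_equal(b$meta$binning, 2)
  expect_error(bin_spatial(cube, 0), "positive")
  expect_warning(bin_spatial(hypercube(array(1, c(1, 5, 2))), 2), "dropping")
  cc <- bin_spatial(hypercube(array(4, c(2, 4, 3))), 2)
  expect_true(all(cc$values == 4))
})

test_that("binning commutes with normalization on noiseless data", {
  set.seed(42)
  raw <- hypercube(array(runif(2 * 8 * 5, 100, 900), c(2, 8, 5)))
  # white/dark vary per band and per slit *bin* (constant inside each bin of
  # 2, as after averaging many reference frames of a smooth field)
  wbin <- rep(c(950, 920, 980, 940), each = 2)
  white <- hypercube(aperm(array(rep(wbin, times = 3 * 5) +
                                   rep(seq(0, 40, by = 10), each = 8 * 3),
                                 c(8, 3, 5)), c(2, 1, 3)))
  dark <- hypercube(array(10, c(3, 8, 5)))
  a <- bin_spatial(normalize_cube(raw, white, dark), 2)
  b <- normalize_cube(bin_spatial(raw, 2), bin_spatial(white, 2),
                      bin_spatial(dark, 2))
  expect_lt(max(abs(a$values - b$values) / pmax(abs(b$values), 1e-9)), 1e-12)
  expect_s3_class(a, "reflectance_cube")
})

test_that("simulate + normalize recovers a known scene reflectance", {
  ins <- instrument_config(n_slit = 24, n_spectral = 64, shot_gain = 0.5,
                           read_noise_sd = 1)
  dm <- dispersion_model(400, 600 / 63, 0, 0, n_pixels = 64)
  led <- default_led_panel()
  rho <- 0.6
  sc <- scene_spec("uniform", bright = rho)
  wh <- scene_spec("uniform", bright = 1)
  raw <- simulate_scan(sc, led, dm, ins, n_lines = 12, seed = 21)
  white <- simulate_scan(wh, led, dm, ins, n_lines = 12, seed = 22)
  r <- normalize_cube(raw, white)
  mid <- 20:45   # bands with solid illumination
  per_band <- apply(r$values[, , mid], 3, mean)
  expect_true(all(abs(per_band - rho) < 0.02))
})
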