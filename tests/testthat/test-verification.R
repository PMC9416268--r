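test_that("region transmittance obeys the ratio identities", {
  v <- array(800, c(30, 30, 6))
  blank <- hypercube(v, wavelength = seq(500, 600, 20))
  same <- transmittance(hypercube(v, wavelength = seq(500, 600, 20)), blank)
  expect_true(all(abs(same$transmittance - 1) < 1e-12))
  halfc <- hypercube(v / 2, wavelength = seq(500, 600, 20))
  half <- transmittance(halfc, blank)
  expect_true(all(abs(half$transmittance - 0.5) < 1e-12))
  # default region is 20 x 20 centred
  expect_error(transmittance(halfc, hypercube(array(1, c(2, 2, 6)))), "extents")
  zero <- v; zero[, , 3] <- 0
  masked <- transmittance(halfc, hypercube(zero, wavelength = seq(500, 600, 20)))
  expect_true(masked$masked[3])
  expect_true(is.na(masked$transmittance[3]))
})

test_that("normalized absorbance matches the formula and its invariance", {
  tt <- tibble::tibble(wavelength_nm = c(500, 600),
                       transmittance = c(0.1, 0.5))
  A <- normalized_absorbance(tt, a = 1)
  expect_equal(A$absorbance, c(1, log(0.5) / log(0.1)))
  expect_equal(max(A$absorbance), 1)

  # (s, 1/s) rescaling leaves the curve unchanged
  wl <- seq(450, 750, by = 2)
  tg <- tibble::tibble(wavelength_nm = wl,
                       transmittance = exp(-1.5 * exp(-((wl - 560) / 40)^2)) * 0.9)
  for (s in c(0.5, 2, 7)) {
    a1 <- normalized_absorbance(tg, a = 1.3)
    tg2 <- dplyr::mutate(tg, transmittance = transmittance * s)
    a2 <- normalized_absorbance(tg2, a = 1.3 / s)
    expect_lt(max(abs(a1$absorbance - a2$absorbance)), 1e-12)
  }
  # single Gaussian absorber peaks at exactly 1 at its centre
  a1 <- normalized_absorbance(tg, a = 1 / max(tg$transmittance))
  expect_equal(a1$wavelength_nm[which.max(a1$absorbance)], 560)
  expect_equal(max(a1$absorbance), 1)

  clear <- tibble::tibble(wavelength_nm = wl, transmittance = rep(1.2, length(wl)))
  expect_error(normalized_absorbance(clear, a = 1), "degenerate")
  expect_error(normalized_absorbance(tt, a = -1))
})

test_that("the normalization factor is recovered by the bounded search", {
  ink <- synthetic_ink_spectrum("red")
  T_ref <- tibble::tibble(wavelength_nm = ink$wavelength_nm,
                          transmittance = ink$value)
  A_ref <- normalized_absorbance(T_ref, a = 1)
  for (s in c(0.8, 1.0, 1.09, 1.19, 1.5)) {
    T_test <- dplyr::mutate(T_ref, transmittance = transmittance / s)
    fit <- fit_normalization_factor(T_test, A_ref)
    expect_equal(fit$a, s, tolerance = 1e-3)
  }
  idfit <- fit_normalization_factor(T_ref, A_ref)
  expect_equal(idfit$a, 1, tolerance = 1e-3)
  expect_lt(idfit$rmse, 1e-6)

  # brute-force grid oracle agrees with the 1-D optimizer
  T_test <- dplyr::mutate(T_ref, transmittance = transmittance / 1.19)
  grid_a <- seq(0.5, 2, by = 1e-4)
  rmse <- vapply(grid_a, function(a) {
    A <- -log(T_test$transmittance * a); A <- A / max(A)
    sqrt(mean((A - A_ref$absorbance)^2))
  }, numeric(1))
  oracle <- grid_a[which.min(rmse)]
  fit <- fit_normalization_factor(T_test, A_ref)
  expect_equal(fit$a, oracle, tolerance = 2e-4)

  far <- dplyr::mutate(T_ref, wavelength_nm = wavelength_nm + 5000)
  expect_error(fit_normalization_factor(far, A_ref), "overlap")
})

test_that("the detector-switch correction enforces continuity", {
  wl <- seq(800, 920, by = 2)
  v <- exp(-((wl - 700) / 150)^2)
  stepped <- v + ifelse(wl >= 860, 0.07, 0)
  spec <- data.frame(wavelength_nm = wl, value = stepped)
  fixed <- correct_detector_switch(spec, 860)
  i <- which(wl == 860)
  expect_lt(abs(fixed$value[i] - fixed$value[i - 1]),
            abs(stepped[i] - stepped[i - 1]))
  # the constant also absorbs the local slope across the 2 nm step
  expect_lt(abs(attr(fixed, "offset") - (-0.07)), 0.015)
  expect_equal(fixed$value[wl < 860], v[wl < 860])   # visible kept verbatim
})

test_that("erythema index maps ratio logic and its invariances", {
  wl <- seq(500, 700, 25)
  nb <- length(wl)
  flat <- reflectance_cube(array(0.4, c(6, 8, nb)), wavelength = wl)
  e0 <- erythema_index(flat)
  expect_true(all(abs(e0) < 1e-12))

  v <- array(0.5, c(6, 8, nb))
  v[, , wl < 600] <- 0.05    # green reflectance a tenth of red
  r10 <- reflectance_cube(v, wavelength = wl)
  e1 <- erythema_index(r10, green_nm = 550, red_nm = 650)
  expect_true(all(abs(e1 - 1) < 1e-12))
  expect_true(all(abs(erythema_index(r10, 550, 650, invert = TRUE) + 1) < 1e-12))

  # vessel phantom: green-absorbing stripe scores above background
  p <- array(0.5, c(10, 20, nb))
  p[, 8:12, wl >= 520 & wl <= 580] <- 0.1
  ph <- reflectance_cube(p, wavelength = wl)
  ep <- erythema_index(ph, 550, 650)
  expect_gt(min(ep[, 8:12]), max(ep[, c(1:7, 13:20)]))

  # uniform illumination scaling cancels in the ratio
  ph2 <- reflectance_cube(p * 0.63, wavelength = wl)
  expect_equal(erythema_index(ph2, 550, 650), erythema_index(ph, 550, 650),
               tolerance = 1e-12, ignore_attr = TRUE)
})
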