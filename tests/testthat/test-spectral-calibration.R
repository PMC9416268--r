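test_that("peak detection refines centroids to sub-pixel accuracy", {
  # discrete delta
  v <- rep(0.1, 200); v[101] <- 100    # pixel 100 (0-based)
  pk <- detect_peaks(v, 0.1)
  expect_equal(pk$centroid_px, 100)

  # sampled Gaussian centred at 100.37 px (oracle: centre by construction,
  # confirmed by dense-grid argmax)
  x <- 0:199
  g <- function(t) exp(-(t - 100.37)^2 / (2 * 4^2))
  dense <- seq(95, 105, by = 1e-4)
  expect_equal(dense[which.max(g(dense))], 100.37, tolerance = 1e-3)
  pk2 <- detect_peaks(g(x), 0.1)
  expect_equal(pk2$centroid_px, 100.37, tolerance = 0.05)

  # two Gaussians 3 px apart with FWHM 10 px: merged, never split into > 2
  s <- 10 / 2.355                      # sigma of a 10-px-FWHM Gaussian
  blend <- exp(-(x - 100)^2 / (2 * s^2)) + exp(-(x - 103)^2 / (2 * s^2))
  pk3 <- detect_peaks(blend, 0.05, min_sep_px = 5)
  expect_lte(nrow(pk3), 2)

  expect_equal(nrow(detect_peaks(rep(3, 50), 0.1)), 0)   # flat -> empty
  expect_error(detect_peaks(1:3, 0.1))
})

test_that("line assignment reaches forty-plus matches and drops ambiguity", {
  peaks <- four_lamp_peaks()
  expect_message(matches <- assign_lines(peaks), "dropped")
  expect_gte(nrow(matches), 40)
  expect_setequal(unique(matches$species), c("Hg/Ar", "H", "He", "Ne"))
  # every match is within the tolerance window of its reference
  fit <- fit_dispersion(matches)
  expect_lt(max(abs(fit$residuals_nm)), 1.5)

  # neon lines a few nm apart resolve only through the model-guided window:
  # with a coarse model supplied the same matches come back
  m2 <- suppressMessages(assign_lines(peaks, coarse = fit$model))
  ne <- m2[m2$species == "Ne", ]
  expect_gte(nrow(ne), 10)
  expect_error(suppressMessages(assign_lines(peaks["He"])), "Hg/Ar or H")
  few <- list("Hg/Ar" = peaks[["Hg/Ar"]][1:2, ], "H" = peaks[["H"]][1, ])
  expect_error(suppressMessages(assign_lines(few)), "anchor|matches")
})

test_that("the cubic fit recovers exact synthetic dispersions", {
  true_coef <- c(340, 0.31, 2e-5, -5e-9)
  x <- seq(50, 1950, length.out = 24)
  matches <- tibble::tibble(
    species = "syn", wavelength_nm = true_coef[1] + true_coef[2] * x +
      true_coef[3] * x^2 + true_coef[4] * x^3,
    centroid_px = x, intensity = 1)
  fit <- fit_dispersion(matches)
  expect_equal(unname(fit$model$coefficients), true_coef, tolerance = 1e-9)
  expect_lt(fit$max_abs_residual_nm, 1e-9)
  expect_equal(fit$max_abs_residual_nm, max(abs(fit$residuals_nm)))
  expect_equal(fit$n_lines, nrow(matches))

  clustered <- dplyr::mutate(matches, centroid_px = 1000 + (x - 1000) * 1e-9)
  expect_error(fit_dispersion(clustered), "conditioning|span")
  expect_error(fit_dispersion(matches[x < 600, ]), "span")
})

test_that("FWHM is measured from interpolated half-max crossings", {
  m <- dispersion_model(0, 0.15, 0, 0, n_pixels = 300)  # 0.15 nm/px sampling
  x <- 0:299
  sigma_px <- 1.0 / 0.15                                # sigma = 1 nm in pixels
  spec <- exp(-(x - 150)^2 / (2 * sigma_px^2))
  fw <- measure_fwhm(spec, 150, m)
  expect_equal(fw$fwhm_nm, 2 * sqrt(2 * log(2)) * 1.0, tolerance = 0.02)
  expect_equal(fw$flag, "ok")

  hot <- rep(0, 50); hot[25] <- 10
  fh <- measure_fwhm(hot, 24)
  expect_lte(fh$fwhm_px, 1)
  expect_equal(fh$flag, "under-resolved")

  # asymmetric line: width comes from the two crossings, not a symmetric fit
  asym <- exp(-(x - 150)^2 / (2 * 4^2))
  asym[x > 150] <- exp(-(x[x > 150] - 150)^2 / (2 * 9^2))
  fa <- measure_fwhm(asym, 150, m)
  half_width_left <- sqrt(2 * log(2)) * 4     # px
  half_width_right <- sqrt(2 * log(2)) * 9
  expect_equal(fa$fwhm_px, half_width_left + half_width_right,
               tolerance = 0.15)
})
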