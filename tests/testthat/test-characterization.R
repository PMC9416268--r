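# characterization round trips use the half-resolution model (1024 spectral
# px over 400-1000 nm) to keep simulation cost down

smile_cube <- function(smile_px, seed, n_lines = 12) {
  ins <- instrument_config(n_slit = 256, n_spectral = 1024,
                           smile_px = smile_px, keystone_px = 0)
  simulate_scan(scene_spec("uniform"), default_led_panel(), half_model(),
                ins, n_lines = n_lines, seed = seed)
}

test_that("spectral smile is recovered and reported in px and nm", {
  sm2 <- spectral_smile(smile_cube(2, seed = 31), model = half_model())
  expect_equal(sm2$max_offset_px, 2, tolerance = 0.3)
  expect_false(sm2$below_pixel)
  expect_false(is.na(sm2$max_offset_nm))
  expect_gt(sm2$max_offset_nm, 0)

  sm0 <- spectral_smile(smile_cube(0, seed = 32), model = half_model())
  expect_lt(sm0$max_offset_px, 0.3)      # below centroiding noise floor
  expect_true(sm0$below_pixel)

  # without a dispersion model: px only
  smx <- spectral_smile(smile_cube(0, seed = 33))
  expect_true(all(is.na(smx$profiles$offset_nm)))
  tiny <- hypercube(array(1, c(1, 8, 16)))
  expect_error(spectral_smile(tiny), "peaks")
})

test_that("keystone edge shifts recover the injected deformation", {
  dm <- half_model()
  key_frame <- function(k) {
    ins <- quiet_config(n_slit = 320, n_spectral = 256, keystone_px = k)
    g <- simulate_scan(scene_spec("square_grid", frequency_lpmm = 0.2,
                                  phase_mm = 0.1),
                       flat_spectrum(),
                       dispersion_model(337.7, 8 * 0.306, 64 * 2.6e-5,
                                        512 * -5.4e-9, n_pixels = 256),
                       ins, n_lines = 1)
    g$values[1, , ]
  }
  k5 <- keystone(key_frame(5))
  expect_equal(k5$max_shift_px, 5, tolerance = 0.5)
  expect_lt(k5$central_half_max_px, 2)

  k0 <- keystone(key_frame(0))
  expect_lt(k0$max_shift_px, 0.5)

  k15 <- keystone(key_frame(1.5))
  expect_lt(k15$max_shift_px, 2)     # "below 2 px over the whole range"
  expect_gt(k15$max_shift_px, 0.8)
})

test_that("homogeneity compares the slit profile against a reference curve", {
  ins <- instrument_config(n_slit = 160, n_spectral = 512)
  dm <- dispersion_model(400, 600 / 511, 0, 0, n_pixels = 512)
  w <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins,
                     n_lines = 8, seed = 41)
  self <- homogeneity(w, ins$vignetting)
  expect_lt(self$max_relative_deviation, 0.01)
  expect_lt(abs(self$peak_offset_px), 2)

  # 10% linear illumination tilt against the nominal curve; the expected
  # deviation follows analytically from the two normalized curves
  tilted <- ins$vignetting * seq(1, 0.9, length.out = 160)
  ins_t <- instrument_config(n_slit = 160, n_spectral = 512,
                             vignetting = tilted / max(tilted))
  wt <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins_t,
                      n_lines = 8, seed = 42)
  tilt <- homogeneity(wt, ins$vignetting)
  obs_true <- tilted / max(tilted)
  ref_true <- ins$vignetting / max(ins$vignetting)
  expected_dev <- max(abs(obs_true - ref_true) / ref_true)
  expect_equal(tilt$max_relative_deviation, expected_dev, tolerance = 0.01)
  expect_gt(tilt$max_relative_deviation, 0.03)   # a 10% tilt is clearly seen

  # decentred vignetting shows up as a peak-position offset
  u <- (seq_len(160) - 80.5) / 79.5
  dec <- 1 - 0.25 * (u - 0.3)^2
  ins_d <- instrument_config(n_slit = 160, n_spectral = 512,
                             vignetting = dec / max(dec))
  wd <- simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins_d,
                      n_lines = 8, seed = 43)
  off <- homogeneity(wd, ins$vignetting)
  expect_equal(off$peak_offset_px, 0.3 * 79.5, tolerance = 3)

  # invariant to global exposure scaling
  w2 <- w; w2$values <- w2$values * 3.7
  expect_equal(homogeneity(w2, ins$vignetting)$max_relative_deviation,
               self$max_relative_deviation, tolerance = 1e-12)
  expect_error(homogeneity(w, ins$vignetting[-1]), "length")
})

test_that("temporal stability reports drift and the warm-up time", {
  dm <- half_model()
  ins <- instrument_config(n_slit = 64, n_spectral = 1024)
  times <- c(1, 3, 5, 10, 20, 30, 45, 60)
  series <- lapply(seq_along(times), function(i)
    simulate_scan(scene_spec("uniform"), default_led_panel(), dm, ins,
                  n_lines = 8, seed = 50 + i, t_min = times[i]))
  st <- temporal_stability(series, times, model = dm)
  expect_equal(st$warmup_min, 30, tolerance = 5)
  sub <- st$table[st$table$t_min %in% c(1, 10), ]
  shifts <- tapply(sub$shift_nm, sub$peak, function(x) abs(diff(x)))
  expect_true(all(shifts < 0.5))
  expect_error(temporal_stability(series, rev(times)), "increasing")
  expect_error(temporal_stability(series[1:2], times[1:2]), ">= 3")

  nod <- instrument_config(n_slit = 64, n_spectral = 1024,
                           drift = list(tau_min = 12, drop_nir = 0,
                                        drop_vis = 0, shift_nm = 0),
                           shot_gain = 0, read_noise_sd = 0)
  s0 <- lapply(c(1, 10, 30), function(t)
    simulate_scan(scene_spec("uniform"), default_led_panel(), dm, nod,
                  n_lines = 1, t_min = t))
  st0 <- temporal_stability(s0, c(1, 10, 30), model = dm)
  expect_true(all(abs(st0$table$shift_px) < 1e-9))
  expect_true(all(abs(st0$table$intensity_ratio - 1) < 1e-9))
})

test_that("focus displacement leaves peak wavelengths in place", {
  dm <- paper_model()
  focus <- lamp_mean_spectrum("He")
  displaced <- lamp_mean_spectrum("He",
                                  config = quiet_config(n_slit = 8,
                                                        slit_fwhm_nm = 4.5))
  # peak positions are compared at the detected-wavelength uncertainty (1 nm)
  same <- focus_consistency(focus, focus, dm, resolution_nm = 1)
  expect_true(all(same$deltas$delta_nm == 0))
  expect_true(same$pass)

  blur <- focus_consistency(focus, displaced, dm, resolution_nm = 1)
  expect_true(blur$pass)
  expect_lt(max(abs(blur$deltas$delta_nm)), 1)

  shifted <- c(rep(0, 7), focus)[1:length(focus)]   # ~ +2 nm at b ~ 0.3
  off <- focus_consistency(focus, shifted, dm, resolution_nm = 1,
                           min_sep_px = 12)
  expect_false(off$pass)
  expect_equal(mean(off$deltas$delta_nm), 7 * 0.306, tolerance = 0.5)
})
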