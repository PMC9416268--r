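#' Default protocol configuration
#'
#' All thresholds carry the protocol defaults: Michelson contrast 0.1 for
#' "discernible", line-matching tolerance 1.5 nm, reflectance clip 1.5,
#' warm-up criterion 1% per 10 min. The instrument block parameterises the
#' simulator used when no on-disk cubes are supplied.
#'
#' @param seed Integer master seed; per-stage seeds are derived from it.
#' @return Nested configuration list (YAML-serialisable).
#' @export
default_protocol_config <- function(seed = 1L) {
  list(
    schema_version = 1L,
    seed = as.integer(seed),
    stages = c("calibrate_spectral", "calibrate_spatial",
               "characterize", "verify"),
    instrument = list(
      n_slit = 160L, n_spectral = 2048L, pitch_mm = 0.12,
      slit_fwhm_nm = 2.9, smile_px = 0.5, keystone_px = 1.5,
      speed_factor = 1.02, spatial_fwhm_px = c(1.5, 2.5),
      shot_gain = 1, read_noise_sd = 2),
    thresholds = list(contrast = 0.1, line_tol_nm = 1.5, clip_max = 1.5,
                      warmup_pct_per_10min = 1, keystone_pass_px = 2,
                      smile_pass_px = 1),
    verify = list(modality_factor = 1.19, ink = "red")
  )
}

protocol_instrument <- function(cfg, ...) {
  ins <- cfg$instrument
  args <- utils::modifyList(
    list(n_slit = ins$n_slit, n_spectral = ins$n_spectral,
         pitch_mm = ins$pitch_mm, slit_fwhm_nm = ins$slit_fwhm_nm,
         smile_px = ins$smile_px, keystone_px = ins$keystone_px,
         speed_factor = ins$speed_factor,
         spatial_fwhm_px = ins$spatial_fwhm_px,
         shot_gain = ins$shot_gain, read_noise_sd = ins$read_noise_sd),
    list(...))
  do.call(instrument_config, args)
}

#' Run the full calibration-characterization-verification protocol
#'
#' Executes the protocol stages in their canonical order — spectral
#' calibration, spatial calibration, characterization (smile, keystone,
#' homogeneity, stability), verification — on simulator-generated data, and
#' assembles one machine-readable report. A stage whose prerequisite failed
#' is skipped (status `"failed"`/`"skipped"`), and the partial report is
#' still returned/written. Every report key is present even for skipped
#' stages (value `NULL`). Characterization reports nm units only when the
#' spectral calibration stage produced a dispersion model; otherwise px
#' only.
#'
#' @param config Configuration list (see [default_protocol_config()]) or a
#'   path to a YAML file with the same structure; `NULL` for defaults.
#' @param seed Master seed (overrides the config seed when given).
#' @param out_dir Optional directory; when given, `report.json` is written
#'   there.
#' @return An object of class `protocol_run`: `stages` status tibble,
#'   `report` nested list, `config`, and the fitted `model` (if any).
#' @export
run_protocol <- function(config = NULL, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_protocol_config(), config %||% list())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  seeds <- cfg$seed + 0:9
  report <- list(schema_version = cfg$schema_version,
                 seed = cfg$seed,
                 spectral = NULL, spatial = NULL,
                 characterization = NULL, verification = NULL,
                 pass = NULL)
  status <- tibble::tibble(stage = cfg$stages, status = "pending",
                           seed = seeds[seq_along(cfg$stages)])
  model <- NULL
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  run_stage <- function(stage, fun) {
    i <- which(status$stage == stage)
    out <- tryCatch(fun(status$seed[i]), error = function(e) {
      log_stage(stage, paste("failed:", conditionMessage(e)))
      structure(list(), class = "stage_failure", message = conditionMessage(e))
    })
    status$status[i] <<- if (inherits(out, "stage_failure")) "failed" else "done"
    if (inherits(out, "stage_failure")) NULL else out
  }

  if ("calibrate_spectral" %in% cfg$stages) {
    report$spectral <- run_stage("calibrate_spectral", function(sd) {
      log_stage("calibrate_spectral", "simulating four-lamp set")
      res <- calibrate_from_lamps(cfg, seed = sd)
      model <<- res$fit$model
      spec <- res$spectra[["He"]]
      pk <- detect_peaks(spec, 0.05, 8)
      fw <- measure_fwhm(spec, pk$centroid_px[which.max(pk$intensity)],
                         model)
      list(coefficients = as.list(res$fit$model$coefficients),
           n_lines = res$fit$n_lines,
           max_abs_residual_nm = res$fit$max_abs_residual_nm,
           fwhm_nm = fw$fwhm_nm)
    })
  }
  if ("calibrate_spatial" %in% cfg$stages) {
    report$spatial <- run_stage("calibrate_spatial", function(sd) {
      log_stage("calibrate_spatial", "Ronchi / USAF / square grid")
      # geometry work needs spatial fidelity, not spectral: use a compact
      # 64-band axis spanning the same 400-1000 nm range
      ins <- protocol_instrument(cfg, n_spectral = 64L)
      led <- default_led_panel()
      dm <- dispersion_model(400, 600 / 63, 0, 0, n_pixels = 64L)
      ron <- simulate_scan(scene_spec("ronchi", frequency_lpmm = 0.5),
                           led, dm, ins, n_lines = 48L, seed = sd)
      img <- apply(ron$values, c(1, 2), mean)
      pitch <- estimate_pixel_pitch(img, 0.5, axis = "slit")
      usaf <- simulate_scan(
        scene_spec("usaf1951",
                   elements = data.frame(group = 0L, element = 1:6)),
        led, dm, ins, n_lines = 220L, seed = sd + 1L)
      rp <- resolving_power(usaf, band = dim(usaf)[3] %/% 2,
                            axis = "slit",
                            elements = usaf$ground_truth$usaf_elements,
                            threshold = cfg$thresholds$contrast)
      grid <- simulate_scan(scene_spec("square_grid", frequency_lpmm = 0.2),
                            led, dm, ins, n_lines = 160L, seed = sd + 2L)
      asp <- scan_aspect(grid, 1 / 0.2)
      list(pitch_slit_mm_px = pitch,
           pitch_report_mm_px = round(pitch, 2),
           resolving = list(group = rp$group, element = rp$element,
                            frequency_lpmm = rp$frequency_lpmm),
           elongation_pct = asp$elongation_pct,
           speed_correction = asp$speed_correction)
    })
  }
  if ("characterize" %in% cfg$stages) {
    report$characterization <- run_stage("characterize", function(sd) {
      log_stage("characterize", "smile / keystone / homogeneity / stability")
      ins <- protocol_instrument(cfg)
      led <- default_led_panel()
      dm_true <- default_dispersion()
      white <- simulate_scan(scene_spec("uniform"), led, dm_true, ins,
                             n_lines = 6L, seed = sd)
      sm <- spectral_smile(white, model = model)
      grid <- simulate_scan(scene_spec("square_grid", frequency_lpmm = 0.2),
                            led, dm_true, ins, n_lines = 1L, seed = sd + 1L)
      ks <- keystone(grid$values[1, , ])
      hom <- homogeneity(white, ins$vignetting)
      times <- c(1, 5, 10, 20, 30, 45, 60)
      series <- lapply(seq_along(times), function(i)
        simulate_scan(scene_spec("uniform"), led, dm_true, ins,
                      n_lines = 2L, seed = sd + 1L + i, t_min = times[i]))
      st <- temporal_stability(series, times, model = model)
      list(smile = list(max_offset_px = sm$max_offset_px,
                        max_offset_nm = sm$max_offset_nm,
                        below_pixel = sm$below_pixel),
           keystone = list(max_shift_px = ks$max_shift_px,
                           central_half_max_px = ks$central_half_max_px),
           homogeneity = list(
             max_relative_deviation = hom$max_relative_deviation,
             peak_offset_px = hom$peak_offset_px, skew = hom$skew),
           stability = list(warmup_min = st$warmup_min,
                            tau_min = st$tau_min))
    })
  }
  if ("verify" %in% cfg$stages) {
    report$verification <- run_stage("verify", function(sd) {
      log_stage("verify", "normalized absorbance and erythema index")
      res <- verify_against_reference(cfg, model %||% default_dispersion(),
                                      seed = sd)
      res
    })
  }

  thr <- cfg$thresholds
  checks <- c(
    spectral = is.null(report$spectral) ||
      report$spectral$max_abs_residual_nm <= 0.5,
    keystone = is.null(report$characterization) ||
      report$characterization$keystone$central_half_max_px <=
        thr$keystone_pass_px,
    smile = is.null(report$characterization) ||
      report$characterization$smile$max_offset_px <= thr$smile_pass_px)
  report$pass <- all(checks)
  run <- structure(list(stages = status, report = report, config = cfg,
                        model = model),
                   class = "protocol_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  run
}

#' @export
print.protocol_run <- function(x, ...) {
  cat("<protocol_run>\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-20s %s\n", x$stages$stage[i], x$stages$status[i]))
  cat(sprintf("  overall pass: %s\n", x$report$pass))
  invisible(x)
}

#' Wavelength calibration from simulated four-lamp scans
#'
#' Simulates the four discharge-lamp scans (Hg/Ar, H, He, Ne) through the
#' configured instrument, detects peaks on the slit-averaged spectra,
#' assigns them iteratively to the bundled reference lines, and fits the
#' cubic dispersion. An optional uniform perturbation of the detected
#' centroids emulates centroiding error for robustness studies.
#'
#' @param cfg Protocol configuration (see [default_protocol_config()]).
#' @param seed Integer seed for the simulated scans.
#' @param centroid_jitter_px Half-width of a uniform perturbation applied to
#'   every detected centroid (0 = none).
#' @param n_lines Scan lines per lamp (averaged).
#' @param n_slit Slit extent used for the lamp scans.
#' @return A list: `spectra` (named list of mean spectra), `peaks`,
#'   `matches` (tibble from [assign_lines()]), `fit`
#'   (a `calibration_fit`).
#' @export
calibrate_from_lamps <- function(cfg = default_protocol_config(), seed = 1L,
                                 centroid_jitter_px = 0,
                                 n_lines = 2L, n_slit = 16L) {
  ins <- protocol_instrument(cfg, n_slit = n_slit, smile_px = 0,
                             keystone_px = 0, spatial_fwhm_px = c(0, 0))
  dm <- default_dispersion()
  species <- c("Hg/Ar", "H", "He", "Ne")
  spectra <- list(); peaks <- list()
  for (k in seq_along(species)) {
    cube <- simulate_scan(scene_spec("uniform"), lamp_spectrum(species[k]),
                          dm, ins, n_lines = n_lines, seed = seed + k)
    spec <- colMeans(scan_average(cube))
    spectra[[species[k]]] <- spec
    pk <- detect_peaks(spec, min_prominence = 0.02, min_sep_px = 6)
    if (centroid_jitter_px > 0)
      pk$centroid_px <- pk$centroid_px +
        stats::runif(nrow(pk), -centroid_jitter_px, centroid_jitter_px)
    peaks[[species[k]]] <- pk
  }
  matches <- assign_lines(peaks, tol_nm = cfg$thresholds$line_tol_nm)
  fit <- fit_dispersion(matches, n_pixels = ins$n_spectral)
  list(spectra = spectra, peaks = peaks, matches = matches, fit = fit)
}

# Transmission verification on synthetic ink cells plus an erythema phantom.
verify_against_reference <- function(cfg, model, seed) {
  ink <- synthetic_ink_spectrum(cfg$verify$ink)
  s_true <- cfg$verify$modality_factor
  ins <- protocol_instrument(cfg, n_slit = 48L, smile_px = 0,
                             keystone_px = 0, speed_factor = 1)
  led <- default_led_panel()
  # HSI arm collects 1/s_true of the reference modality's light
  t_fun <- as_spectrum(ink)
  sample_scene <- scene_spec("uniform",
                             bright = function(l) t_fun(l) / s_true)
  blank_scene <- scene_spec("uniform", bright = 1)
  sample <- simulate_scan(sample_scene, led, model, ins, n_lines = 24L,
                          seed = seed)
  blank <- simulate_scan(blank_scene, led, model, ins, n_lines = 24L,
                         seed = seed + 1L)
  sample$wavelength <- band_wavelengths(model, dim(sample)[3])
  blank$wavelength <- sample$wavelength
  tt <- transmittance(sample, blank)
  tt <- tt[tt$wavelength_nm >= 420 & tt$wavelength_nm <= 980, ]
  A_ref <- normalized_absorbance(
    tibble::tibble(wavelength_nm = ink$wavelength_nm,
                   transmittance = ink$value), a = 1)
  fit <- fit_normalization_factor(tt, A_ref)

  # erythema phantom: green-absorbing stripe on a neutral background
  wl <- seq(450, 750, by = 10)
  nb <- length(wl)
  vals <- array(0.5, c(24L, 32L, nb))
  stripe <- 12:20
  g_idx <- which(wl >= 500 & wl <= 590)
  vals[, stripe, g_idx] <- 0.12
  phantom <- reflectance_cube(vals, wavelength = wl)
  emap <- erythema_index(phantom)
  inside <- mean(emap[, stripe]); outside <- mean(emap[, -stripe])
  list(normalization_factor = fit$a, rmse = fit$rmse,
       peak_deltas_nm = fit$agreement$delta_nm,
       erythema = list(stripe_mean = inside, background_mean = outside,
                       contrast = inside - outside))
}

#' Synthetic ink transmittance spectrum
#'
#' A smooth synthetic stand-in for the collimated transmittance of a dyed
#' sample cell (it is generated from Gaussian absorbance bands, not measured
#' data): "red" ink absorbs in the green around 530 nm, "blue" ink in the
#' orange/red around 610 nm.
#'
#' @param kind `"red"` or `"blue"`.
#' @return Data frame `wavelength_nm`, `value` (transmittance) on a 1-nm
#'   grid over 400-1000 nm.
#' @export
synthetic_ink_spectrum <- function(kind = c("red", "blue")) {
  kind <- match.arg(kind)
  wl <- 400:1000
  A <- if (kind == "red")
    1.6 * exp(-((wl - 530) / 55)^2) + 0.5 * exp(-((wl - 420) / 40)^2)
  else
    1.4 * exp(-((wl - 610) / 60)^2) + 0.4 * exp(-((wl - 680) / 45)^2)
  data.frame(wavelength_nm = wl, value = exp(-A) * 0.92 + 0.02)
}

#' Write simulator fixture sets for tests and demos
#'
#' Generates ENVI cube pairs plus a JSON ground-truth sidecar for a named
#' scenario. Refuses to write into a non-empty directory unless
#' `overwrite = TRUE`. The same seed reproduces identical fixtures.
#'
#' @param kind One of `"lamps"`, `"ronchi"`, `"usaf"`, `"square_grid"`,
#'   `"white_stack"`, `"drift_series"`, `"ink_cells"`.
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow writing into a non-empty directory.
#' @param config Optional protocol configuration (see
#'   [default_protocol_config()]).
#' @return Character vector of written cube paths, invisibly.
#' @export
make_fixtures <- function(kind = c("lamps", "ronchi", "usaf", "square_grid",
                                   "white_stack", "drift_series", "ink_cells"),
                          seed = 1L, out_dir, overwrite = FALSE,
                          config = NULL) {
  kind <- match.arg(kind)
  cfg <- utils::modifyList(default_protocol_config(seed), config %||% list())
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !overwrite)
    stop("output directory is not empty; pass overwrite = TRUE", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ins <- protocol_instrument(cfg, n_slit = 32L)
  dm <- default_dispersion()
  led <- default_led_panel()
  paths <- character(0)
  emit <- function(cube, name) {
    p <- file.path(out_dir, name)
    write_cube(cube, p)
    gt <- cube$ground_truth
    gt$vignetting <- NULL   # long vector; keep the sidecar compact
    jsonlite::write_json(gt, paste0(p, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    paths <<- c(paths, p)
  }
  switch(kind,
    lamps = for (sp in c("Hg/Ar", "H", "He", "Ne"))
      emit(simulate_scan(scene_spec("uniform"), lamp_spectrum(sp), dm, ins,
                         n_lines = 2L, seed = seed + match(sp, c("Hg/Ar", "H", "He", "Ne"))),
           paste0("lamp_", gsub("/", "", sp), ".raw")),
    ronchi = emit(simulate_scan(scene_spec("ronchi", frequency_lpmm = 0.5),
                                led, dm, ins, n_lines = 48L, seed = seed),
                  "ronchi.raw"),
    usaf = emit(simulate_scan(
      scene_spec("usaf1951", elements = data.frame(group = 0L, element = 1:3)),
      led, dm, ins, n_lines = 96L, seed = seed), "usaf.raw"),
    square_grid = emit(simulate_scan(
      scene_spec("square_grid", frequency_lpmm = 0.2), led, dm, ins,
      n_lines = 160L, seed = seed), "square_grid.raw"),
    white_stack = emit(simulate_scan(scene_spec("uniform"), led, dm, ins,
                                     n_lines = 20L, seed = seed),
                       "white_stack.raw"),
    drift_series = for (t in c(1, 10, 30, 60))
      emit(simulate_scan(scene_spec("uniform"), led, dm, ins, n_lines = 2L,
                         seed = seed + t, t_min = t),
           sprintf("white_t%03d.raw", t)),
    ink_cells = for (k in c("red", "blue")) {
      ink <- synthetic_ink_spectrum(k)
      emit(simulate_scan(
        scene_spec("uniform",
                   bright = data.frame(wavelength_nm = ink$wavelength_nm,
                                       value = ink$value)),
        led, dm, ins, n_lines = 24L, seed = seed + nchar(k)),
        sprintf("ink_%s.raw", k))
    })
  invisible(paths)
}
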