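# Shared builders for simulator-based tests. Sizes are kept small: spectral
# work uses the full 2048-px axis only where the cubic fit needs its span;
# geometry work uses compact axes.

paper_model <- function() default_dispersion()

# compact dispersion covering 400-1000 nm on few bands, for spatial tests
coarse_model <- function(n = 64L) dispersion_model(400, 600 / (n - 1), 0, 0,
                                                   n_pixels = n)

# half-resolution spectral axis spanning the same range as the paper-scale
# model, for characterization round-trips (b doubles, c x4, d x8)
half_model <- function() dispersion_model(337.7, 2 * 0.306, 4 * 2.6e-5,
                                          8 * -5.4e-9, n_pixels = 1024L)

quiet_config <- function(...) {
  instrument_config(shot_gain = 0, read_noise_sd = 0, ...)
}

# noiseless mean spectrum of a lamp through the forward model
lamp_mean_spectrum <- function(species, model = paper_model(),
                               config = quiet_config(n_slit = 8L)) {
  cube <- simulate_scan(scene_spec("uniform"), lamp_spectrum(species),
                        model, config, n_lines = 1L)
  colMeans(scan_average(cube))
}

# simulated four-lamp peak sets (noiseless unless config says otherwise)
four_lamp_peaks <- function(model = paper_model(),
                            config = quiet_config(n_slit = 8L),
                            n_lines = 1L, seed = NULL) {
  peaks <- list()
  for (sp in c("Hg/Ar", "H", "He", "Ne")) {
    cube <- simulate_scan(scene_spec("uniform"), lamp_spectrum(sp), model,
                          config, n_lines = n_lines,
                          seed = if (is.null(seed)) NULL else seed + match(sp, c("Hg/Ar", "H", "He", "Ne")))
    spec <- colMeans(scan_average(cube))
    peaks[[sp]] <- detect_peaks(spec, min_prominence = 0.02, min_sep_px = 6)
  }
  peaks
}
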