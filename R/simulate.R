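#' Instrument configuration for the forward simulator
#'
#' Full parameterisation of the simulated push-broom spectrograph: detector
#' geometry, slit spectral broadening, smile, keystone, vignetting, noise,
#' warm-up drift and scanning-speed mismatch.
#'
#' @param n_slit,n_spectral Detector extents in pixels (each >= 8).
#' @param pixel_pitch_um Detector pixel pitch (default 3.45 um).
#' @param pitch_mm Object-plane size of one slit pixel (mm/px); 0.12 is
#'   typical of a 17 mm lens, 0.03 of a 50 mm lens at working distance.
#' @param slit_fwhm_nm Spectral FWHM of the slit image (instrumental
#'   broadening), default 2.9 nm.
#' @param smile_px Smile amplitude: spectral-pixel offset at the slit edges
#'   relative to the slit centre (quadratic bow).
#' @param keystone_px Keystone: spatial shift in px at the field edge between
#'   the extreme and the central wavelength (wavelength-linear slit
#'   magnification).
#' @param vignetting Relative illumination per slit pixel in `(0, 1]`:
#'   a vector of length `n_slit`, a function of the normalised field
#'   coordinate in `[-1, 1]`, or `NULL` for the default smooth falloff
#'   `1 - 0.25 u^2`.
#' @param peak_counts Counts at the brightest detector pixel for a white
#'   scene at unit exposure.
#' @param shot_gain Counts per photo-electron for the scaled-Poisson shot
#'   noise (0 disables shot noise).
#' @param read_noise_sd Gaussian read noise sigma in counts (0 disables).
#' @param drift Warm-up drift parameters: `tau_min` (time constant,
#'   minutes), `drop_nir`/`drop_vis` (fractional intensity drop from
#'   switch-on to settled for NIR/visible LEDs), `shift_nm` (initial
#'   wavelength offset, decaying with the same time constant).
#' @param speed_factor Scanning-speed mismatch; 1.06 produces ~6% elongation
#'   along the scan axis.
#' @param spatial_fwhm_px Spatial PSF FWHM in px, length-2 vector
#'   `c(slit, scan)` (anisotropy is typical: the slit width limits the scan
#'   axis).
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(n_slit = 320L, n_spectral = 2048L,
                              pixel_pitch_um = 3.45, pitch_mm = 0.12,
                              slit_fwhm_nm = 2.9,
                              smile_px = 0, keystone_px = 0,
                              vignetting = NULL,
                              peak_counts = 4000, shot_gain = 1,
                              read_noise_sd = 2,
                              drift = list(tau_min = 11, drop_nir = 0.2,
                                           drop_vis = 0.03, shift_nm = 0.4),
                              speed_factor = 1,
                              spatial_fwhm_px = c(slit = 0, scan = 0)) {
  n_slit <- as.integer(n_slit); n_spectral <- as.integer(n_spectral)
  if (n_slit < 8L || n_spectral < 8L)
    stop("detector extents must be >= 8 px", call. = FALSE)
  stopifnot(slit_fwhm_nm > 0, peak_counts > 0, speed_factor > 0,
            shot_gain >= 0, read_noise_sd >= 0)
  u <- (seq_len(n_slit) - (n_slit + 1) / 2) / ((n_slit - 1) / 2)
  vig <- if (is.null(vignetting)) 1 - 0.25 * u^2
         else if (is.function(vignetting)) vignetting(u)
         else vignetting
  if (length(vig) != n_slit)
    stop("vignetting profile length must equal n_slit", call. = FALSE)
  if (any(vig <= 0) || any(vig > 1))
    stop("vignetting profile must lie in (0, 1]", call. = FALSE)
  spatial_fwhm_px <- rep_len(spatial_fwhm_px, 2L)
  structure(list(n_slit = n_slit, n_spectral = n_spectral,
                 pixel_pitch_um = pixel_pitch_um, pitch_mm = pitch_mm,
                 slit_fwhm_nm = slit_fwhm_nm, smile_px = smile_px,
                 keystone_px = keystone_px, vignetting = vig,
                 peak_counts = peak_counts, shot_gain = shot_gain,
                 read_noise_sd = read_noise_sd, drift = drift,
                 speed_factor = speed_factor,
                 spatial_fwhm_px = spatial_fwhm_px),
            class = "instrument_config")
}

#' Simulate a push-broom scan
#'
#' Forward model: per scan line, the detector frame is
#' `illumination x scene reflectance x vignetting`, mapped through the cubic
#' dispersion with a smile offset `delta(y) = s ((y - y_c)/y_c)^2` (spectral
#' pixels), a keystone slit magnification linear in wavelength (reported as
#' px shift at the field edge), Gaussian slit-PSF spectral broadening
#' (applied analytically to the illumination components), and optional
#' scaled-Poisson shot noise plus Gaussian read noise. A ground-truth record
#' of every injected parameter is attached to the returned cube.
#'
#' @param scene A [scene_spec()].
#' @param illum An `illumination_spec` ([lamp_spectrum()],
#'   [led_panel_spectrum()]).
#' @param model A [dispersion_model()].
#' @param config An [instrument_config()].
#' @param n_lines Number of scan lines.
#' @param seed Integer seed; mandatory whenever noise is enabled.
#' @param t_min Minutes since illumination switch-on (`Inf` = settled; warm-up
#'   drift applies otherwise).
#' @param exposure Exposure scale factor (counts are linear in it).
#' @return A raw-counts [hypercube()] with a `ground_truth` element.
#' @export
simulate_scan <- function(scene, illum, model, config, n_lines = 8L,
                          seed = NULL, t_min = Inf, exposure = 1) {
  stopifnot(inherits(scene, "scene_spec"), inherits(illum, "illumination_spec"),
            inherits(model, "dispersion_model"),
            inherits(config, "instrument_config"))
  noisy <- config$shot_gain > 0 || config$read_noise_sd > 0
  if (noisy && is.null(seed))
    stop("`seed` is required when noise is enabled", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_slit <- config$n_slit; n_spec <- config$n_spectral

  # fine wavelength grid covering the detector plus margins
  x_lo <- -3; x_hi <- n_spec + 2
  lam_lo <- wavelength_of_pixel(model, x_lo)
  lam_hi <- wavelength_of_pixel(model, x_hi)
  step <- min(local_dispersion(model, c(0, n_spec - 1)) / 4,
              fwhm_to_sigma(config$slit_fwhm_nm) / 2)
  grid <- seq(lam_lo, lam_hi, by = step)
  dr <- drift_state(config, t_min, illum)
  dens <- illumination_density(illum, grid, extra_fwhm_nm = config$slit_fwhm_nm,
                               scale = dr$scale, shift_nm = dr$shift_nm)
  count_scale <- exposure * config$peak_counts / max(dens)

  # scene raster; scan pitch shrinks when the stage moves slower than nominal
  pitch_scan <- config$pitch_mm / config$speed_factor
  rc <- render_scene(scene, c(n_lines, n_slit), config$pitch_mm, pitch_scan)
  frac <- rc$frac
  frac <- gaussian_blur_mat(frac, config$spatial_fwhm_px[1], margin = 1L)  # along slit
  frac <- gaussian_blur_mat(frac, config$spatial_fwhm_px[2], margin = 2L)  # along scan

  yc <- (n_slit + 1) / 2
  y <- seq_len(n_slit)
  u <- (y - yc) / ((n_slit - 1) / 2)   # normalised field coordinate, +-1 at edges
  delta <- config$smile_px * u^2
  xs <- seq_len(n_spec) - 1          # 0-based spectral pixel
  # effective wavelength seen by (slit y, spectral x): lambda(x - delta(y))
  xeff <- outer(-delta, xs, `+`)     # n_slit x n_spec
  lam_eff <- wavelength_of_pixel(model, xeff)
  ill_mat <- matrix(stats::approx(grid, dens, xout = lam_eff, rule = 2)$y,
                    n_slit, n_spec)
  rb <- matrix(rc$bright(as.vector(lam_eff)), n_slit, n_spec)
  rd <- matrix(rc$dark(as.vector(lam_eff)), n_slit, n_spec)

  # keystone: distortion-like image displacement, odd and quadratic in the
  # field coordinate (u|u|) and linear in wavelength; `keystone_px` is the
  # shift at the field edge between the central and the extreme wavelength
  lam_band <- wavelength_of_pixel(model, xs)
  lam_mid <- mean(range(lam_band)); lam_half <- diff(range(lam_band)) / 2
  g <- (lam_band - lam_mid) / lam_half
  ys <- y - config$keystone_px * outer(u * abs(u), g)  # n_slit x n_spec

  values <- array(0, c(n_lines, n_slit, n_spec))
  for (i in seq_len(n_lines)) {
    fk <- matrix(stats::approx(y, frac[i, ], xout = ys, rule = 2)$y,
                 n_slit, n_spec)
    refl <- fk * rb + (1 - fk) * rd
    frame <- config$vignetting * ill_mat * refl * count_scale
    if (config$shot_gain > 0) {
      g <- config$shot_gain
      frame[] <- g * stats::rpois(length(frame), frame / g)
    }
    if (config$read_noise_sd > 0)
      frame <- frame + stats::rnorm(length(frame), 0, config$read_noise_sd)
    values[i, , ] <- pmax(frame, 0)
  }

  truth <- list(
    seed = seed, t_min = t_min, exposure = exposure,
    dispersion = unname(model$coefficients),
    smile_px = config$smile_px, keystone_px = config$keystone_px,
    speed_factor = config$speed_factor,
    vignetting = config$vignetting,
    slit_fwhm_nm = config$slit_fwhm_nm,
    spatial_fwhm_px = config$spatial_fwhm_px,
    drift = dr, scene_kind = scene$kind,
    illumination = illum$table,
    usaf_elements = rc$elements
  )
  cube <- hypercube(values, meta = list(
    exposure_ms = exposure, binning = 1,
    pixel_pitch_um = config$pixel_pitch_um,
    speed_factor = config$speed_factor))
  cube$ground_truth <- truth
  cube
}
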