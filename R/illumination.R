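#' Emission-line spectrum of a calibration lamp
#'
#' Returns the bundled air-wavelength line list for one of the four
#' gas-discharge calibration tubes (mercury with argon fill gas, hydrogen,
#' helium, neon). The table was compiled from standard atomic air
#' wavelengths; relative intensities are representative values used for
#' rank-order line identification, not radiometric claims.
#'
#' @param species One of `"Hg/Ar"`, `"H"`, `"He"`, `"Ne"`.
#' @return An `illumination_spec` of kind `"lines"`, whose `table` element is
#'   a tibble with columns `species`, `wavelength_nm`, `intensity`.
#' @export
lamp_spectrum <- function(species) {
  tab <- lamp_line_table()
  if (!species %in% unique(tab$species))
    stop("unknown lamp species '", species, "'; available: ",
         paste(unique(tab$species), collapse = ", "), call. = FALSE)
  lines <- tab[tab$species == species, ]
  illumination_spec(kind = "lines",
                    table = tibble::tibble(species = lines$species,
                                           wavelength_nm = lines$wavelength_air_nm,
                                           intensity = lines$relative_intensity))
}

#' Bundled reference line table
#'
#' All lamp lines for the four supported species, as shipped in
#' `extdata/lamp_lines.csv`.
#' @return Tibble with columns `species`, `wavelength_air_nm`,
#'   `relative_intensity`.
#' @export
lamp_line_table <- function() {
  path <- system.file("extdata", "lamp_lines.csv", package = "hsical",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tab$wavelength_air_nm > 350, tab$wavelength_air_nm < 1100),
            all(tab$relative_intensity > 0))
  tibble::as_tibble(tab)
}

#' Monochromatic (laser-like) illumination
#'
#' A single emission line, e.g. a He-Ne laser scattered off PTFE for
#' resolution testing or an unknown line for wavelength-recovery checks.
#'
#' @param wavelength_nm Line wavelength (350-1100 nm).
#' @param intensity Relative intensity.
#' @return An `illumination_spec` of kind `"lines"`.
#' @export
monochromatic_spectrum <- function(wavelength_nm, intensity = 1) {
  illumination_spec(kind = "lines",
                    table = tibble::tibble(species = "mono",
                                           wavelength_nm = wavelength_nm,
                                           intensity = intensity))
}

illumination_spec <- function(kind, table) {
  stopifnot(kind %in% c("lines", "led", "flat"))
  if (kind != "flat") {
    wl <- if (kind == "lines") table$wavelength_nm else table$center_nm
    if (any(wl < 350 | wl > 1100))
      stop("illumination wavelengths must lie within 350-1100 nm", call. = FALSE)
  }
  structure(list(kind = kind, table = table), class = "illumination_spec")
}

#' Spectrally flat broadband illumination
#'
#' An idealised halogen-like source with constant spectral density, useful
#' for aberration measurements that need contrast at every band.
#'
#' @param level Relative spectral density.
#' @return An `illumination_spec` of kind `"flat"`.
#' @export
flat_spectrum <- function(level = 1) {
  illumination_spec(kind = "flat", table = tibble::tibble(power = level))
}

#' @export
print.illumination_spec <- function(x, ...) {
  cat(sprintf("<illumination_spec> kind=%s, %d components\n",
              x$kind, nrow(x$table)))
  invisible(x)
}

#' LED panel spectrum from Gaussian components
#'
#' Models a multi-LED illumination panel as a sum of Gaussian emission
#' profiles. The default panel ([default_led_panel()]) spans 400-1000 nm.
#'
#' @param components Data frame with columns `center_nm`, `fwhm_nm`, `power`
#'   (relative radiant power; all positive).
#' @return An `illumination_spec` of kind `"led"`.
#' @export
led_panel_spectrum <- function(components) {
  components <- tibble::as_tibble(components)
  if (nrow(components) < 1L)
    stop("at least one LED component is required", call. = FALSE)
  stopifnot(all(c("center_nm", "fwhm_nm", "power") %in% names(components)),
            all(components$fwhm_nm > 0), all(components$power > 0))
  illumination_spec(kind = "led", table = components)
}

#' Default 10-LED panel covering 400-1000 nm
#'
#' Ten equal-power Gaussian LEDs with 35 nm FWHM on centres from 420 to
#' 990 nm: the summed spectrum stays above 10% of its peak over the whole
#' 400-1000 nm range, while neighbouring LEDs overlap little enough that
#' their apparent peak wavelengths stay stable (below about half a nm) when
#' visible and NIR emitters warm up at different rates. Illustrative of a
#' biomedical HSI illumination panel, not a model of any particular
#' hardware.
#' @return An `illumination_spec` of kind `"led"`.
#' @export
default_led_panel <- function() {
  led_panel_spectrum(tibble::tibble(
    center_nm = seq(420, 990, length.out = 10),
    fwhm_nm = 35,
    power = 1
  ))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Spectral density of an illumination spec on a wavelength grid
#'
#' Evaluates the illumination as a sum of Gaussian profiles, optionally
#' convolved with an instrumental Gaussian of FWHM `extra_fwhm_nm` (for lamp
#' delta lines this is the only width; for LEDs the widths add in
#' quadrature). Per-component intensity scales and a global wavelength shift
#' implement warm-up drift.
#'
#' @param illum An `illumination_spec`.
#' @param lambda_nm Wavelength grid (nm).
#' @param extra_fwhm_nm Instrumental broadening FWHM added in quadrature.
#' @param scale Scalar or per-component intensity scale.
#' @param shift_nm Scalar or per-component wavelength shift.
#' @return Numeric vector of spectral density on `lambda_nm` (arbitrary
#'   units).
#' @export
illumination_density <- function(illum, lambda_nm, extra_fwhm_nm = 0,
                                 scale = 1, shift_nm = 0) {
  stopifnot(inherits(illum, "illumination_spec"))
  tab <- illum$table
  if (illum$kind == "flat")
    return(rep(tab$power[1] * mean(scale), length(lambda_nm)))
  n <- nrow(tab)
  scale <- rep_len(scale, n)
  shift_nm <- rep_len(shift_nm, n)
  if (illum$kind == "lines") {
    centers <- tab$wavelength_nm
    sigma <- rep_len(max(fwhm_to_sigma(extra_fwhm_nm), 1e-6), n)
    power <- tab$intensity
  } else {
    centers <- tab$center_nm
    sigma <- sqrt(fwhm_to_sigma(tab$fwhm_nm)^2 + fwhm_to_sigma(extra_fwhm_nm)^2)
    power <- tab$power
  }
  out <- numeric(length(lambda_nm))
  for (i in seq_len(n))
    out <- out + scale[i] * power[i] *
      exp(-((lambda_nm - centers[i] - shift_nm[i])^2) / (2 * sigma[i]^2))
  out
}

#' Warm-up drift state of the illumination at time t
#'
#' LED output settles exponentially after switch-on: the peak intensity
#' follows `I(t) = I_inf + (I0 - I_inf) exp(-t / tau)` and the peak
#' wavelength shift decays with the same time constant. Near-infrared LEDs
#' (centre >= 700 nm) drift with the full configured amplitude; visible LEDs
#' with a much smaller one, reflecting the weaker warm-up behaviour of
#' visible emitters.
#'
#' @param config An [instrument_config()] (its `drift` element is used).
#' @param t Minutes since the illumination was switched on (`Inf` = fully
#'   settled reference state).
#' @param illum Optional `illumination_spec`; when given, per-component
#'   scales and shifts are returned, otherwise the NIR values.
#' @return A tibble with columns `component`, `center_nm`, `scale`,
#'   `shift_nm` (one row of `center_nm = NA` when `illum` is missing).
#' @export
drift_state <- function(config, t, illum = NULL) {
  stopifnot(t >= 0 || is.infinite(t))
  dr <- config$drift
  decay <- if (is.infinite(t)) 0 else exp(-t / dr$tau_min)
  centers <- if (is.null(illum) || illum$kind == "flat") NA_real_
             else if (illum$kind == "led") illum$table$center_nm
             else illum$table$wavelength_nm
  nir <- is.na(centers) | centers >= 700
  drop <- ifelse(nir, dr$drop_nir, dr$drop_vis)
  tibble::tibble(
    component = seq_along(centers),
    center_nm = centers,
    # I(t) = I_inf + (I0 - I_inf) exp(-t/tau), with I0 = 1 and I_inf = 1 - drop
    scale = (1 - drop) + drop * decay,
    shift_nm = ifelse(nir, dr$shift_nm, dr$shift_nm / 4) * decay
  )
}
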