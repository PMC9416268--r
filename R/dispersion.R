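#' Cubic dispersion model of an imaging spectrograph
#'
#' The wavelength falling on spectral detector pixel `x` is modelled as the
#' cubic polynomial `lambda(x) = a + b x + c x^2 + d x^3`, the third-order
#' expansion used when the spectrograph geometry is not known precisely.
#' The pixel index `x` is 0-based (the first spectral pixel is `x = 0`);
#' cube band `k` (1-based, R convention) corresponds to `x = k - 1`.
#'
#' @param a Intercept, nm.
#' @param b Linear dispersion, nm/px.
#' @param c Quadratic term, nm/px^2.
#' @param d Cubic term, nm/px^3.
#' @param covariance Optional 4x4 symmetric positive semi-definite
#'   coefficient covariance matrix.
#' @param n_pixels Spectral extent over which monotonicity is checked
#'   (default 2048).
#' @return An object of class `dispersion_model`.
#' @examples
#' m <- dispersion_model(337.7, 0.306, 2.6e-5, -5.4e-9)
#' wavelength_of_pixel(m, c(0, 1000))
#' @export
dispersion_model <- function(a, b, c, d, covariance = NULL, n_pixels = 2048L) {
  coef <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(is.finite(coef)))
  x <- seq(0, n_pixels - 1L, length.out = 512L)
  lam <- a + b * x + c * x^2 + d * x^3
  if (any(diff(lam) <= 0))
    stop("dispersion must be strictly increasing over the spectral extent",
         call. = FALSE)
  if (!is.null(covariance)) {
    covariance <- as.matrix(covariance)
    stopifnot(identical(dim(covariance), c(4L, 4L)))
    if (max(abs(covariance - t(covariance))) > 1e-8 * max(1, abs(covariance)))
      stop("covariance must be symmetric", call. = FALSE)
    if (min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("covariance must be positive semi-definite", call. = FALSE)
  }
  structure(list(coefficients = coef, covariance = covariance,
                 n_pixels = as.integer(n_pixels), pixel_convention = "0-based"),
            class = "dispersion_model")
}

#' Paper-scale default dispersion
#'
#' Coefficients typical of a 400-1000 nm visible/NIR imaging spectrograph on
#' a 2048-pixel spectral axis (a = 337.7 nm, b = 0.306 nm/px,
#' c = 2.6e-5 nm/px^2, d = -5.4e-9 nm/px^3).
#' @return A [dispersion_model()].
#' @export
default_dispersion <- function() {
  dispersion_model(337.7, 0.306, 2.6e-5, -5.4e-9)
}

#' @export
print.dispersion_model <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<dispersion_model> lambda(x) = %.4g + %.4g x + %.4g x^2 + %.4g x^3 (x %s)\n",
              co["a"], co["b"], co["c"], co["d"], x$pixel_convention))
  invisible(x)
}

#' Wavelength of a (fractional) spectral pixel
#'
#' @param model A [dispersion_model()].
#' @param x Fractional 0-based spectral pixel index (vectorised).
#' @return Wavelength(s) in nm.
#' @export
wavelength_of_pixel <- function(model, x) {
  stopifnot(inherits(model, "dispersion_model"))
  co <- model$coefficients
  co[["a"]] + co[["b"]] * x + co[["c"]] * x^2 + co[["d"]] * x^3
}

#' Spectral pixel of a wavelength (numeric inverse of the dispersion)
#'
#' @param model A [dispersion_model()].
#' @param wavelength Wavelength(s) in nm, inside the calibrated range.
#' @return Fractional 0-based pixel index(es); round-trips through
#'   [wavelength_of_pixel()] to 1e-9 nm.
#' @export
pixel_of_wavelength <- function(model, wavelength) {
  stopifnot(inherits(model, "dispersion_model"))
  lo <- -1; hi <- model$n_pixels
  rng <- wavelength_of_pixel(model, c(lo, hi))
  vapply(wavelength, function(w) {
    if (w < rng[1] || w > rng[2])
      stop(sprintf("wavelength %.2f nm outside calibrated range %.1f-%.1f nm",
                   w, rng[1], rng[2]), call. = FALSE)
    stats::uniroot(function(x) wavelength_of_pixel(model, x) - w,
                   lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

#' Local dispersion (nm per pixel) at a spectral pixel
#'
#' Derivative `b + 2 c x + 3 d x^2`, used to convert pixel widths and offsets
#' to nm.
#' @inheritParams wavelength_of_pixel
#' @return nm/px at `x`.
#' @export
local_dispersion <- function(model, x) {
  stopifnot(inherits(model, "dispersion_model"))
  co <- model$coefficients
  co[["b"]] + 2 * co[["c"]] * x + 3 * co[["d"]] * x^2
}

#' Wavelength axis for a detector of given spectral extent
#'
#' @param model A [dispersion_model()].
#' @param n_spectral Number of spectral pixels.
#' @return Numeric vector of nm at x = 0, ..., n_spectral - 1.
#' @export
band_wavelengths <- function(model, n_spectral) {
  wavelength_of_pixel(model, seq_len(n_spectral) - 1)
}

#' @export
tidy.dispersion_model <- function(x, ...) {
  se <- if (is.null(x$covariance)) rep(NA_real_, 4) else sqrt(diag(x$covariance))
  tibble::tibble(
    term = c("a", "b", "c", "d"),
    estimate = unname(x$coefficients),
    std.error = se,
    unit = c("nm", "nm/px", "nm/px^2", "nm/px^3")
  )
}
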