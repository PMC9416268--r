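#' Collimated transmittance of a sample region
#'
#' Per-band mean over a spatially homogeneous region of `sample / blank`
#' (the blank is the unobstructed beam). The default region is the central
#' 20 x 20 pixels. Bands where the blank is zero anywhere in the region are
#' masked (NA with `masked = TRUE`), not silently dropped.
#'
#' @param sample_cube,blank_cube [hypercube()]s sharing extents.
#' @param scan,slit Index vectors selecting the region; default centred
#'   20 x 20 px (clipped to the cube).
#' @return Tibble: `wavelength_nm` (NA when uncalibrated), `band`,
#'   `transmittance`, `masked`.
#' @export
transmittance <- function(sample_cube, blank_cube, scan = NULL, slit = NULL) {
  stopifnot(inherits(sample_cube, "hypercube"),
            inherits(blank_cube, "hypercube"))
  d <- dim(sample_cube)
  if (!identical(dim(blank_cube), d))
    stop("sample and blank cubes must share extents", call. = FALSE)
  center_region <- function(n, width = 20L) {
    half <- min(width, n) %/% 2L
    lo <- max(1L, n %/% 2L - half + 1L)
    seq(lo, min(n, lo + min(width, n) - 1L))
  }
  if (is.null(scan)) scan <- center_region(d[1])
  if (is.null(slit)) slit <- center_region(d[2])
  s <- sample_cube$values[scan, slit, , drop = FALSE]
  b <- blank_cube$values[scan, slit, , drop = FALSE]
  masked <- apply(b, 3L, function(x) any(x <= 0))
  ratio <- s / ifelse(b > 0, b, NA_real_)
  tr <- apply(ratio, 3L, mean)
  tr[masked] <- NA_real_
  tibble::tibble(
    wavelength_nm = if (is.null(sample_cube$wavelength)) NA_real_
                    else sample_cube$wavelength,
    band = seq_len(d[3]),
    transmittance = tr,
    masked = masked)
}

#' Normalized absorbance of a transmittance spectrum
#'
#' `A(lambda) = -ln(T(lambda) * a)` scaled by its maximum so the strongest
#' absorption equals exactly 1 (`A_tilde = A / max(A)`). The normalization
#' factor `a` accounts for modalities collecting different amounts of light;
#' the result is invariant to any `(s, 1/s)` rescaling of `(T, a)`. The sign
#' convention (absorbance positive, peak = 1) is recorded in the result.
#'
#' @param T_spec Data frame with columns `wavelength_nm` and `transmittance`
#'   (strictly positive where used).
#' @param a Normalization factor (> 0).
#' @return Tibble `wavelength_nm`, `absorbance` with attributes
#'   `normalization_factor` and `sign_convention`.
#' @export
normalized_absorbance <- function(T_spec, a = 1) {
  stopifnot(a > 0,
            all(c("wavelength_nm", "transmittance") %in% names(T_spec)))
  keep <- is.finite(T_spec$transmittance)
  wl <- T_spec$wavelength_nm[keep]
  tt <- T_spec$transmittance[keep]
  if (any(tt * a <= 0))
    stop("T * a must be positive on the grid", call. = FALSE)
  A <- -log(tt * a)
  m <- max(A)
  if (m <= 0)
    stop("degenerate input: no absorption anywhere (max A <= 0)",
         call. = FALSE)
  out <- tibble::tibble(wavelength_nm = wl, absorbance = A / m)
  attr(out, "normalization_factor") <- a
  attr(out, "sign_convention") <- "absorbance positive; strongest absorption = 1"
  out
}

#' Fit the normalization factor against a reference absorbance
#'
#' Finds the factor `a` minimising the RMSE between
#' `normalized_absorbance(T_test, a)` and a reference normalized absorbance
#' over their common wavelength range (1-D bounded search). Also reports
#' per-feature peak-wavelength differences between the two curves.
#'
#' @param T_test Transmittance tibble (`wavelength_nm`, `transmittance`).
#' @param A_ref Normalized-absorbance tibble (`wavelength_nm`,
#'   `absorbance`), max = 1.
#' @param interval Search interval for `a` (default `c(0.5, 2)`).
#' @return A list: `a`, `rmse`, `agreement` tibble of matched absorbance
#'   peaks (`ref_nm`, `test_nm`, `delta_nm`).
#' @export
fit_normalization_factor <- function(T_test, A_ref, interval = c(0.5, 2)) {
  lo <- max(min(T_test$wavelength_nm), min(A_ref$wavelength_nm))
  hi <- min(max(T_test$wavelength_nm), max(A_ref$wavelength_nm))
  if (hi <= lo) stop("no overlapping wavelength range", call. = FALSE)
  grid <- A_ref$wavelength_nm[A_ref$wavelength_nm >= lo &
                                A_ref$wavelength_nm <= hi]
  t_i <- stats::approx(T_test$wavelength_nm, T_test$transmittance, grid)$y
  a_i <- stats::approx(A_ref$wavelength_nm, A_ref$absorbance, grid)$y
  ok <- is.finite(t_i) & is.finite(a_i) & t_i > 0
  t_i <- t_i[ok]; a_i <- a_i[ok]; grid <- grid[ok]
  obj <- function(a) {
    A <- -log(t_i * a)
    m <- max(A)
    if (m <= 0) return(1e6)
    sqrt(mean((A / m - a_i)^2))
  }
  opt <- stats::optimize(obj, interval = interval, tol = 1e-8)
  a_hat <- opt$minimum
  A_test <- -log(t_i * a_hat); A_test <- A_test / max(A_test)
  peaks_ref <- detect_peaks(a_i, min_prominence = 0.1, min_sep_px = 5)
  peaks_test <- detect_peaks(A_test, min_prominence = 0.1, min_sep_px = 5)
  step <- stats::median(diff(grid))
  agreement <- purrr::map_dfr(seq_len(nrow(peaks_ref)), function(p) {
    d <- abs(peaks_test$centroid_px - peaks_ref$centroid_px[p])
    if (!length(d)) return(NULL)
    j <- which.min(d)
    tibble::tibble(
      ref_nm = grid[1] + peaks_ref$centroid_px[p] * step,
      test_nm = grid[1] + peaks_test$centroid_px[j] * step,
      delta_nm = (peaks_test$centroid_px[j] - peaks_ref$centroid_px[p]) * step)
  })
  list(a = a_hat, rmse = opt$objective, agreement = agreement)
}

#' Continuity correction at a reference spectrometer detector switch
#'
#' Grating spectrometers switching detectors mid-range (e.g. Si to InGaAs at
#' 860 nm) can show a step; this utility keeps the visible segment and adds
#' a constant offset to the NIR segment so the curve is continuous at the
#' switch wavelength.
#'
#' @param spec Data frame `wavelength_nm`, `value`.
#' @param switch_nm Switch wavelength (default 860).
#' @return The spectrum with the NIR segment offset; attribute `offset`
#'   records the applied constant.
#' @export
correct_detector_switch <- function(spec, switch_nm = 860) {
  stopifnot(all(c("wavelength_nm", "value") %in% names(spec)))
  vis <- spec$wavelength_nm < switch_nm
  if (!any(vis) || all(vis)) return(spec)
  last_vis <- spec$value[max(which(vis))]
  first_nir <- spec$value[min(which(!vis))]
  offset <- last_vis - first_nir
  spec$value[!vis] <- spec$value[!vis] + offset
  attr(spec, "offset") <- offset
  spec
}

#' Erythema index map from a reflectance cube
#'
#' The log ratio of reflectance in the red and green bands,
#' `E = log10(R_red / R_green)` per pixel: a dimensionless proxy for tissue
#' blood content (haemoglobin absorbs green strongly, so redder, more
#' perfused tissue scores higher). Zero-reflectance pixels are masked (NA).
#' Invariant to uniform illumination scaling.
#'
#' @param cube A [reflectance_cube()] with a calibrated wavelength axis.
#' @param green_nm,red_nm Band wavelengths (defaults 560 and 650 nm).
#' @param invert Use `log10(R_green / R_red)` instead (some conventions).
#' @return Scan-by-slit numeric matrix of the index, with attribute `bands`
#'   giving the actual wavelengths used.
#' @export
erythema_index <- function(cube, green_nm = 560, red_nm = 650,
                           invert = FALSE) {
  g <- extract_band(cube, green_nm)
  r <- extract_band(cube, red_nm)
  gv <- ifelse(g > 0, g, NA_real_)
  rv <- ifelse(r > 0, r, NA_real_)
  e <- if (invert) log10(gv / rv) else log10(rv / gv)
  attr(e, "bands") <- c(green_nm = attr(g, "wavelength_nm"),
                        red_nm = attr(r, "wavelength_nm"))
  e
}
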