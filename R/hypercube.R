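#' Hypercube container for push-broom acquisitions
#'
#' A push-broom system records one spatial line and the full spectral axis per
#' frame; scanning builds the second spatial axis. A `hypercube` therefore
#' holds a 3-D array of detector counts indexed `(scan_line, slit_pixel,
#' spectral_pixel)` (1-based, as is idiomatic in R), an optional calibrated
#' wavelength axis, and acquisition metadata.
#'
#' @param values Numeric 3-D array, dimensions `(scan, slit, spectral)`.
#'   All values must be finite and non-negative.
#' @param wavelength Optional numeric vector of nm per spectral pixel;
#'   must be strictly increasing and of length `dim(values)[3]`.
#' @param meta Named list of acquisition metadata. Recognised fields:
#'   `focal_length_mm`, `exposure_ms`, `binning`, `pixel_pitch_um`,
#'   `speed_factor`. Unknown fields are kept verbatim.
#'
#' @return An object of class `hypercube`.
#' @examples
#' cube <- hypercube(array(1, c(2, 4, 8)), wavelength = seq(400, 470, 10))
#' dim(cube)
#' @export
hypercube <- function(values, wavelength = NULL, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (scan, slit, spectral)", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all three extents must be >= 1", call. = FALSE)
  if (!all(is.finite(values)))
    stop("cube values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("cube values must be non-negative", call. = FALSE)
  if (!is.null(wavelength)) {
    wavelength <- as.numeric(wavelength)
    if (length(wavelength) != dim(values)[3L])
      stop("wavelength axis length (", length(wavelength),
           ") != spectral extent (", dim(values)[3L], ")", call. = FALSE)
    if (any(diff(wavelength) <= 0))
      stop("wavelength axis must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, wavelength = wavelength, meta = meta),
            class = "hypercube")
}

#' Reflectance cube
#'
#' Same layout as [hypercube()] but holding dimensionless reflectance or
#' transmittance values in `[0, clip_max]`. Produced by [normalize_cube()].
#'
#' @inheritParams hypercube
#' @param clip_max Upper clip bound; values above it are an error here
#'   (clipping is applied by [normalize_cube()], not by the constructor).
#' @param mask Optional logical array of the same dimensions flagging
#'   invalid pixels (non-positive white-dark denominator, clipped values).
#' @return Object of class `c("reflectance_cube", "hypercube")`.
#' @export
reflectance_cube <- function(values, wavelength = NULL, meta = list(),
                             clip_max = 1.5, mask = NULL) {
  if (!all(is.finite(values)))
    stop("reflectance values must be finite", call. = FALSE)
  if (any(values < 0) || any(values > clip_max))
    stop("reflectance values must lie in [0, clip_max]", call. = FALSE)
  cube <- hypercube(values, wavelength, meta)
  cube$clip_max <- clip_max
  cube$mask <- mask
  class(cube) <- c("reflectance_cube", "hypercube")
  cube
}

#' @export
dim.hypercube <- function(x) dim(x$values)

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<%s> %d scan x %d slit x %d spectral\n",
              class(x)[1], d[1], d[2], d[3]))
  if (!is.null(x$wavelength))
    cat(sprintf("  wavelength axis: %.1f-%.1f nm (%d bands)\n",
                min(x$wavelength), max(x$wavelength), length(x$wavelength)))
  else cat("  wavelength axis: <uncalibrated>\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a raw cube to reflectance with white and dark references
#'
#' Computes `R = (S - Dbar) / (Wbar - Dbar)` per pixel and band, where `Dbar`
#' and `Wbar` are the dark and white cubes averaged over their scan lines
#' (white/dark stacks of 20-30 frames are typical). Pixels where the
#' denominator is non-positive are flagged in the returned mask rather than
#' silently set to NaN; reflectance is clipped to `[0, clip_max]` so specular
#' outliers stay visible, with clipped pixels also flagged.
#'
#' @param raw Raw [hypercube()] of sample counts.
#' @param white White-reference [hypercube()]; slit/spectral extents must
#'   match `raw`.
#' @param dark Dark [hypercube()], or `NULL` for no dark subtraction
#'   (equivalent to an all-zero dark stack).
#' @param clip_max Reflectance clip bound (default 1.5).
#' @return A [reflectance_cube()] whose `mask` element flags invalid or
#'   clipped pixels.
#' @export
normalize_cube <- function(raw, white, dark = NULL, clip_max = 1.5) {
  stopifnot(inherits(raw, "hypercube"), inherits(white, "hypercube"))
  d <- dim(raw)
  if (is.null(dark))
    dark <- hypercube(array(0, c(1L, d[2], d[3])))
  stopifnot(inherits(dark, "hypercube"))
  if (!identical(dim(white)[2:3], d[2:3]) || !identical(dim(dark)[2:3], d[2:3]))
    stop("white/dark cubes must share slit and spectral extents with `raw`",
         call. = FALSE)
  wbar <- colMeans(white$values, dims = 1L)   # slit x spectral
  dbar <- colMeans(dark$values, dims = 1L)
  denom <- wbar - dbar
  bad2d <- denom <= 0
  denom[bad2d] <- NA_real_

  vals <- raw$values
  for (i in seq_len(d[1])) vals[i, , ] <- (vals[i, , ] - dbar) / denom
  mask <- !is.finite(vals)
  mask <- mask | vals < 0 | vals > clip_max
  vals[!is.finite(vals)] <- 0
  vals <- pmin(pmax(vals, 0), clip_max)

  n_bad <- sum(bad2d)
  if (n_bad > 0)
    warning(sprintf("%d detector pixels had non-positive white-dark denominator; flagged in mask",
                    n_bad), call. = FALSE)
  reflectance_cube(vals, wavelength = raw$wavelength, meta = raw$meta,
                   clip_max = clip_max, mask = mask)
}

#' Extract the band nearest to a requested wavelength
#'
#' Returns the single band whose calibrated wavelength is nearest the request
#' (ties broken toward the lower index). The request must fall within the
#' axis range extended by half a band spacing on either end.
#'
#' @param cube A [hypercube()] with a wavelength axis.
#' @param wavelength Requested wavelength in nm.
#' @return A scan-by-slit numeric matrix with attribute `wavelength_nm`
#'   giving the actual band wavelength.
#' @export
extract_band <- function(cube, wavelength) {
  stopifnot(inherits(cube, "hypercube"))
  wl <- cube$wavelength
  if (is.null(wl))
    stop("cube has no wavelength axis; calibrate first", call. = FALSE)
  half <- stats::median(diff(wl)) / 2
  if (wavelength < wl[1] - half || wavelength > wl[length(wl)] + half)
    stop(sprintf("requested %.1f nm outside axis range %.1f-%.1f nm",
                 wavelength, wl[1], wl[length(wl)]), call. = FALSE)
  dist <- abs(wl - wavelength)
  idx <- which(dist == min(dist))[1]  # tie -> lower index
  band <- cube$values[, , idx, drop = TRUE]
  if (is.null(dim(band)))
    band <- matrix(band, nrow = dim(cube)[1])
  attr(band, "wavelength_nm") <- wl[idx]
  band
}

#' Bin a cube along the slit axis
#'
#' Averages slit pixels in non-overlapping groups of `factor` (Table-style 2x
#' spatial binning). If the slit extent is not divisible by `factor` the
#' remainder rows are dropped with a warning. The binning factor is recorded
#' (multiplicatively) in `meta$binning`.
#'
#' @param cube A [hypercube()].
#' @param factor Positive integer bin size.
#' @return Binned [hypercube()].
#' @export
bin_spatial <- function(cube, factor) {
  stopifnot(inherits(cube, "hypercube"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("`factor` must be a positive integer", call. = FALSE)
  if (factor == 1L) return(cube)
  d <- dim(cube)
  keep <- (d[2] %/% factor) * factor
  if (keep < d[2])
    warning(sprintf("slit extent %d not divisible by %d; dropping %d rows",
                    d[2], factor, d[2] - keep), call. = FALSE)
  v <- cube$values[, seq_len(keep), , drop = FALSE]
  dim(v) <- c(d[1], factor, keep %/% factor, d[3])
  v <- apply(v, c(1, 3, 4), mean)
  meta <- cube$meta
  meta$binning <- (if (is.null(meta$binning)) 1 else meta$binning) * factor
  out <- hypercube(v, wavelength = cube$wavelength, meta = meta)
  class(out) <- class(cube)
  if (inherits(cube, "reflectance_cube")) out$clip_max <- cube$clip_max
  out
}

#' Average a cube over its scan lines
#'
#' @param cube A [hypercube()].
#' @return Slit-by-spectral matrix of scan-averaged values.
#' @export
scan_average <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  colMeans(cube$values, dims = 1L)
}

#' Mean spectrum of a cube region
#'
#' @param cube A [hypercube()].
#' @param scan,slit Index vectors selecting the region (defaults: all).
#' @return A tibble with columns `band`, `wavelength_nm` (NA when
#'   uncalibrated) and `value`.
#' @export
region_spectrum <- function(cube, scan = NULL, slit = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube)
  if (is.null(scan)) scan <- seq_len(d[1])
  if (is.null(slit)) slit <- seq_len(d[2])
  sub <- cube$values[scan, slit, , drop = FALSE]
  spec <- apply(sub, 3L, mean)
  tibble::tibble(
    band = seq_len(d[3]),
    wavelength_nm = if (is.null(cube$wavelength)) NA_real_ else cube$wavelength,
    value = spec
  )
}
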