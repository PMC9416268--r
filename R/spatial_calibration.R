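#' Spatial frequency of a USAF1951 element
#'
#' `f = 2^(group + (element - 1)/6)` line pairs per mm.
#'
#' @param group Integer group number (may be negative).
#' @param element Element number in 1..6.
#' @return Frequency in lp/mm (vectorised).
#' @examples
#' round(usaf_frequency(0, 5), 2)  # 1.59
#' round(usaf_frequency(2, 3), 2)  # 5.04
#' @export
usaf_frequency <- function(group, element) {
  if (any(!element %in% 1:6))
    stop("`element` must be in 1..6", call. = FALSE)
  2^(group + (element - 1) / 6)
}

#' Bar width corresponding to a spatial frequency
#'
#' With frequency defined as `1/d = 1/(2w)` lp/mm, the bar (feature) width is
#' `w = 1/(2f)` mm.
#'
#' @param frequency Frequency in lp/mm (> 0).
#' @return Width in mm.
#' @export
feature_size <- function(frequency) {
  stopifnot(all(frequency > 0))
  1 / (2 * frequency)
}

#' Estimate the object-plane pixel pitch from a bar-target image
#'
#' Either directly as `span_mm / span_px`, or from a Ronchi image: the bar
#' period in pixels is the mean spacing of sub-pixel 50%-amplitude edge
#' crossings along the chosen axis, and
#' `pitch = (1 / frequency) / period_px`. Invariant to global intensity
#' scaling and to contrast inversion.
#'
#' @param image Scan-by-slit matrix (e.g. one band of a cube), or `NULL`
#'   when using the direct form.
#' @param known_frequency_lpmm Target frequency in lp/mm.
#' @param axis `"slit"` (columns) or `"scan"` (rows).
#' @param span_mm,span_px Direct form: a known physical distance and its
#'   measured extent in pixels.
#' @return Pitch in mm/px (full precision; round for reporting).
#' @export
estimate_pixel_pitch <- function(image = NULL, known_frequency_lpmm = NULL,
                                 axis = c("slit", "scan"),
                                 span_mm = NULL, span_px = NULL) {
  if (!is.null(span_mm) && !is.null(span_px)) {
    stopifnot(span_mm > 0, span_px > 0)
    return(span_mm / span_px)
  }
  axis <- match.arg(axis)
  stopifnot(is.matrix(image), !is.null(known_frequency_lpmm),
            known_frequency_lpmm > 0)
  profile <- if (axis == "slit") colMeans(image) else rowMeans(image)
  cross <- half_crossings(profile)
  if (length(cross) < 7L)
    stop("fewer than 3 full periods visible along the ", axis, " axis",
         call. = FALSE)
  period_px <- 2 * mean(diff(cross))
  (1 / known_frequency_lpmm) / period_px
}

#' Smallest discernible USAF1951 element in a band image
#'
#' For each rendered element, samples the profile across its three bars along
#' the requested axis and computes the Michelson contrast
#' `(I_max - I_min)/(I_max + I_min)` for each of the two gaps against its
#' adjacent bars. An element is discernible when both gap contrasts reach
#' `threshold`. The two axes are evaluated independently (push-broom
#' resolutions differ along and across the scan).
#'
#' @param cube A [reflectance_cube()] (or raw [hypercube()]) of a USAF scene.
#' @param band Wavelength in nm (needs a calibrated axis) or, when the cube
#'   is uncalibrated, a 1-based band index.
#' @param axis `"slit"` or `"scan"`: axis along which the bars alternate.
#' @param elements Geometry tibble as produced by [render_scene()] (the
#'   simulator attaches it to `ground_truth$usaf_elements`).
#' @param threshold Michelson contrast criterion (default 0.1, recorded in
#'   the result).
#' @return A list: `group`, `element`, `frequency_lpmm` of the finest
#'   discernible element (all `NA` with `discernible = FALSE` when none
#'   passes), and `contrast` — the per-element contrast tibble.
#' @export
resolving_power <- function(cube, band, axis = c("slit", "scan"), elements,
                            threshold = 0.1) {
  axis <- match.arg(axis)
  stopifnot(inherits(cube, "hypercube"), is.data.frame(elements))
  img <- if (!is.null(cube$wavelength)) extract_band(cube, band)
         else cube$values[, , band, drop = TRUE]
  el <- elements[elements$orientation == axis, ]
  rows <- purrr::pmap(el, function(group, element, orientation, bar_width_mm,
                                   scan_lo, scan_hi, slit_lo, slit_hi,
                                   bar_width_px, ...) {
    w <- bar_width_px
    if (axis == "slit") {
      r <- round(scan_lo):round(scan_hi)
      r <- r[r >= 1 & r <= nrow(img)]
      prof_x <- seq(max(1, floor(slit_lo - w)), min(ncol(img), ceiling(slit_hi + w)))
      profile <- colMeans(img[r, prof_x, drop = FALSE])
      origin <- slit_lo
    } else {
      cidx <- round(slit_lo):round(slit_hi)
      cidx <- cidx[cidx >= 1 & cidx <= ncol(img)]
      prof_x <- seq(max(1, floor(scan_lo - w)), min(nrow(img), ceiling(scan_hi + w)))
      profile <- rowMeans(img[prof_x, cidx, drop = FALSE])
      origin <- scan_lo
    }
    # bar centres at origin + (0.5, 2.5, 4.5) w; gap centres at (1.5, 3.5) w
    at <- function(centers) vapply(centers, function(p) {
      sel <- prof_x >= p - w / 4 & prof_x <= p + w / 4
      if (!any(sel)) NA_real_ else mean(profile[sel])
    }, numeric(1))
    bars <- at(origin + c(0.5, 2.5, 4.5) * w)
    gaps <- at(origin + c(1.5, 3.5) * w)
    c1 <- (gaps[1] - max(bars[1:2])) / (gaps[1] + max(bars[1:2]))
    c2 <- (gaps[2] - max(bars[2:3])) / (gaps[2] + max(bars[2:3]))
    tibble::tibble(group = group, element = element,
                   frequency_lpmm = usaf_frequency(group, element),
                   contrast_min = min(c1, c2, na.rm = FALSE),
                   discernible = is.finite(c1) && is.finite(c2) &&
                     min(c1, c2) >= threshold)
  })
  tab <- dplyr::bind_rows(rows)
  ok <- tab[tab$discernible, ]
  if (!nrow(ok))
    return(list(group = NA_integer_, element = NA_integer_,
                frequency_lpmm = NA_real_, discernible = FALSE,
                threshold = threshold, contrast = tab))
  best <- ok[which.max(ok$frequency_lpmm), ]
  list(group = best$group, element = best$element,
       frequency_lpmm = best$frequency_lpmm, discernible = TRUE,
       threshold = threshold, contrast = tab)
}

#' Scan-axis elongation and corrective speed factor from a square grid
#'
#' Measures the grid period per axis (mean spacing of 50%-amplitude edge
#' crossings of the axis profiles) on a spectrally integrated image and
#' reports the elongation `(scan_period / slit_period - 1) * 100%` and the
#' corrective scanning-speed factor `slit_period / scan_period`.
#'
#' @param cube A [hypercube()] of a square-grid scene.
#' @param grid_period_mm Grid period (informational, returned in the record).
#' @return A list: `elongation_pct`, `speed_correction`, `period_px`
#'   (named vector per axis).
#' @export
scan_aspect <- function(cube, grid_period_mm = NA_real_) {
  stopifnot(inherits(cube, "hypercube"))
  img <- apply(cube$values, c(1, 2), mean)   # scan x slit
  periods <- vapply(c(slit = "slit", scan = "scan"), function(ax) {
    profile <- if (ax == "slit") colMeans(img) else rowMeans(img)
    cross <- half_crossings(profile)
    if (length(cross) < 7L)
      stop("fewer than 3 full grid periods along the ", ax, " axis",
           call. = FALSE)
    2 * mean(diff(cross))
  }, numeric(1))
  list(elongation_pct = (periods[["scan"]] / periods[["slit"]] - 1) * 100,
       speed_correction = periods[["slit"]] / periods[["scan"]],
       period_px = periods, grid_period_mm = grid_period_mm)
}
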