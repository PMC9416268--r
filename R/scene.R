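#' Scene specification for the forward simulator
#'
#' Describes the object-plane target imaged by the simulated system. All
#' geometry is in millimetres on the object plane.
#'
#' @param kind One of `"uniform"`, `"ronchi"`, `"usaf1951"`, `"square_grid"`,
#'   `"two_region_sample"`.
#' @param frequency_lpmm Line frequency for `ronchi`/`square_grid`
#'   (line pairs per mm, `1/d = 1/(2w)` with `w` the bar width).
#' @param axis For `ronchi`: axis along which the pattern alternates
#'   (`"slit"` or `"scan"`).
#' @param elements For `usaf1951`: data frame with columns `group`,
#'   `element` listing the three-bar elements to render (both orientations
#'   are always rendered).
#' @param bright,dark Reflectance (or transmittance) of the bright and dark
#'   regions: a scalar in `[0, 1]`, a `data.frame(wavelength_nm, value)`, or
#'   a function of nm. For `two_region_sample` these are the spectra of
#'   region A (left half of the slit) and region B.
#' @param phase_mm Pattern phase offset in mm (bar targets).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(kind = c("uniform", "ronchi", "usaf1951", "square_grid",
                                "two_region_sample"),
                       frequency_lpmm = NULL, axis = c("slit", "scan"),
                       elements = NULL, bright = 0.99, dark = 0.02,
                       phase_mm = 0) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (kind %in% c("ronchi", "square_grid")) {
    if (is.null(frequency_lpmm) || frequency_lpmm <= 0)
      stop("`frequency_lpmm` must be positive for bar/grid targets",
           call. = FALSE)
  }
  if (kind == "usaf1951") {
    if (is.null(elements))
      elements <- data.frame(group = 0L, element = 1:6)
    stopifnot(all(elements$element %in% 1:6))
  }
  structure(list(kind = kind, frequency_lpmm = frequency_lpmm, axis = axis,
                 elements = elements, bright = bright, dark = dark,
                 phase_mm = phase_mm),
            class = "scene_spec")
}

#' Render a scene to a per-pixel bright-region coverage map
#'
#' Rasterises the target geometry at the requested object-plane pixel
#' pitches. Region boundaries are area-averaged into edge pixels (exact for
#' the axis-aligned geometry used here), so the map is band-limited only by
#' the pixel aperture; any further blur is the instrument's spatial PSF,
#' applied by [simulate_scan()].
#'
#' @param scene A [scene_spec()].
#' @param extents Integer vector `c(n_scan, n_slit)`.
#' @param pitch_slit_mm,pitch_scan_mm Object-plane pixel pitch per axis.
#' @return A list with `frac` (`n_scan x n_slit` matrix, fraction of the
#'   pixel covered by the bright/A region), `bright` and `dark` spectrum
#'   functions, and for USAF targets an `elements` tibble of rendered
#'   geometry (positions in fractional pixels).
#' @export
render_scene <- function(scene, extents, pitch_slit_mm, pitch_scan_mm = pitch_slit_mm) {
  stopifnot(inherits(scene, "scene_spec"), length(extents) == 2L,
            pitch_slit_mm > 0, pitch_scan_mm > 0)
  n_scan <- extents[1]; n_slit <- extents[2]
  elements_tab <- NULL
  frac <- switch(
    scene$kind,
    uniform = matrix(1, n_scan, n_slit),
    two_region_sample = {
      # region A occupies the left half of the slit
      covA <- interval_coverage(n_slit, pitch_slit_mm, 0,
                                n_slit * pitch_slit_mm / 2)
      matrix(rep(covA, each = n_scan), n_scan, n_slit)
    },
    ronchi = {
      period <- 1 / scene$frequency_lpmm
      if (period / 2 < 2 * min(pitch_slit_mm, pitch_scan_mm))
        warning("Ronchi half-period under 2 px; target is under-resolved",
                call. = FALSE)
      if (scene$axis == "slit") {
        dark_cov <- square_wave_coverage(n_slit, pitch_slit_mm, period,
                                         scene$phase_mm)
        matrix(rep(1 - dark_cov, each = n_scan), n_scan, n_slit)
      } else {
        dark_cov <- square_wave_coverage(n_scan, pitch_scan_mm, period,
                                         scene$phase_mm)
        matrix(rep(1 - dark_cov, times = n_slit), n_scan, n_slit)
      }
    },
    square_grid = {
      period <- 1 / scene$frequency_lpmm
      bright_slit <- 1 - square_wave_coverage(n_slit, pitch_slit_mm, period,
                                              scene$phase_mm)
      bright_scan <- 1 - square_wave_coverage(n_scan, pitch_scan_mm, period,
                                              scene$phase_mm)
      outer(bright_scan, bright_slit)   # bright squares on dark background
    },
    usaf1951 = {
      out <- render_usaf(scene$elements, n_scan, n_slit,
                         pitch_slit_mm, pitch_scan_mm)
      elements_tab <- out$elements
      out$frac
    }
  )
  list(frac = frac,
       bright = as_spectrum(scene$bright),
       dark = as_spectrum(scene$dark),
       elements = elements_tab)
}

# Three-bar USAF elements, both orientations side by side, stacked along the
# scan axis. Bars are dark (coverage removed from a bright background).
render_usaf <- function(elements, n_scan, n_slit, pitch_slit, pitch_scan) {
  frac <- matrix(1, n_scan, n_slit)
  rows <- list()
  y0 <- 2 * pitch_scan   # top margin, mm
  x_margin <- 2 * pitch_slit
  for (i in seq_len(nrow(elements))) {
    g <- elements$group[i]; e <- elements$element[i]
    w <- feature_size(usaf_frequency(g, e))
    len <- 5 * w
    # orientation "slit": pattern alternates along the slit axis
    for (orient in c("slit", "scan")) {
      x0 <- if (orient == "slit") x_margin else x_margin + len + 4 * w
      bar_starts <- (0:2) * 2 * w
      if (orient == "slit") {
        cov_scan <- interval_coverage(n_scan, pitch_scan, y0, y0 + len)
        cov_bars <- Reduce(`+`, lapply(bar_starts, function(b)
          interval_coverage(n_slit, pitch_slit, x0 + b, x0 + b + w)))
        frac <- frac - outer(cov_scan, cov_bars)
      } else {
        cov_bars <- Reduce(`+`, lapply(bar_starts, function(b)
          interval_coverage(n_scan, pitch_scan, y0 + b, y0 + b + w)))
        cov_slit <- interval_coverage(n_slit, pitch_slit, x0, x0 + len)
        frac <- frac - outer(cov_bars, cov_slit)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, element = e, orientation = orient,
        bar_width_mm = w,
        # fractional pixel coordinates (1-based centres) of the element box
        scan_lo = y0 / pitch_scan + 0.5, scan_hi = (y0 + len) / pitch_scan + 0.5,
        slit_lo = x0 / pitch_slit + 0.5, slit_hi = (x0 + len) / pitch_slit + 0.5,
        bar_width_px = w / (if (orient == "slit") pitch_slit else pitch_scan)
      )
    }
    y0 <- y0 + len + 3 * w
  }
  frac <- pmin(pmax(frac, 0), 1)
  list(frac = frac, elements = dplyr::bind_rows(rows))
}
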