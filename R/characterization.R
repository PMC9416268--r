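#' Spectral smile profile from a spatially uniform scene
#'
#' For every slit pixel, the centroid of each identifiable illumination peak
#' is located; the value at the slit centre is subtracted; and the resulting
#' offset profile is smoothed with a centred running average (window
#' truncated at the edges). Offsets are reported in spectral pixels and,
#' when a dispersion model is given, in nm through the local dispersion.
#'
#' @param cube A [hypercube()] of a uniform (white/PTFE-like) scene under an
#'   illumination with at least 3 identifiable peaks.
#' @param model Optional [dispersion_model()] for nm conversion.
#' @param window Running-average window in slit pixels (default 50).
#' @param min_prominence,min_sep_px Peak detection parameters (see
#'   [detect_peaks()]).
#' @return An object of class `smile_report`: `profiles` tibble
#'   (`slit_px`, `peak`, `peak_center_px`, `offset_px`, `offset_nm`),
#'   `max_offset_px`, `max_offset_nm`, and `below_pixel` — whether the
#'   maximum offset is below one spectral pixel.
#' @export
spectral_smile <- function(cube, model = NULL, window = 50,
                           min_prominence = 0.05, min_sep_px = 20) {
  stopifnot(inherits(cube, "hypercube"))
  m <- scan_average(cube)                       # slit x spectral
  n_slit <- nrow(m)
  yc <- round((n_slit + 1) / 2)
  ref <- detect_peaks(m[yc, ], min_prominence, min_sep_px)
  if (nrow(ref) < 3L)
    stop("fewer than 3 identifiable illumination peaks at the slit centre",
         call. = FALSE)
  # LED-scale peaks span tens of pixels: track each one per slit row with a
  # centre-of-mass centroid over the region above 70% of the local maximum
  cent <- matrix(NA_real_, n_slit, nrow(ref))
  for (p in seq_len(nrow(ref))) {
    i0 <- ref$pixel[p] + 1L
    for (y in seq_len(n_slit))
      cent[y, p] <- refine_centroid_com(m[y, ], i0, frac = 0.7,
                                        search = min_sep_px)
  }
  raw_off <- sweep(cent, 2L, cent[yc, ])
  # smoothing is a local quadratic over `window` slit pixels: equivalent to
  # the usual running average against noise, but unbiased at the slit edges,
  # where a quadratic bow takes its maximum
  smoothed <- apply(raw_off, 2L, local_quad_smooth, window = window)
  profiles <- purrr::map_dfr(seq_len(nrow(ref)), function(p) {
    tibble::tibble(
      slit_px = seq_len(n_slit), peak = p,
      peak_center_px = ref$centroid_px[p],
      offset_px = smoothed[, p],
      offset_nm = if (is.null(model)) NA_real_
                  else smoothed[, p] * local_dispersion(model, ref$centroid_px[p]))
  })
  max_px <- max(abs(smoothed), na.rm = TRUE)
  max_nm <- if (is.null(model)) NA_real_ else {
    nm_per_px <- local_dispersion(model, ref$centroid_px)
    max(abs(sweep(smoothed, 2L, nm_per_px, `*`)), na.rm = TRUE)
  }
  structure(list(profiles = profiles, max_offset_px = max_px,
                 max_offset_nm = max_nm, below_pixel = max_px < 1,
                 window = window),
            class = "smile_report")
}

#' @export
print.smile_report <- function(x, ...) {
  cat(sprintf("<smile_report> max |offset| = %.3f px%s%s\n", x$max_offset_px,
              if (is.na(x$max_offset_nm)) ""
              else sprintf(" (%.3f nm)", x$max_offset_nm),
              if (x$below_pixel) " [below pixel size]" else ""))
  invisible(x)
}

#' Keystone from a single hyperspectral frame of a bar/grid scene
#'
#' Per spectral band, each high-contrast edge along the slit axis is located
#' as a sub-pixel 50%-amplitude crossing; its shift relative to the position
#' at the central band measures the wavelength-dependent magnification.
#' Bands whose profile amplitude falls below `contrast_min` (relative to the
#' best band) are skipped with a recorded count.
#'
#' @param frame Slit-by-spectral matrix (one scan line), e.g.
#'   `cube$values[1, , ]`.
#' @param band_step Evaluate every `band_step`-th band (default chosen to
#'   give about 100 bands).
#' @param contrast_min Minimum relative profile amplitude.
#' @return An object of class `keystone_report`: `shifts` tibble (`band`,
#'   `edge`, `edge_pos_px`, `shift_px`), `max_shift_px`,
#'   `central_half_max_px`, `n_skipped_bands`.
#' @export
keystone <- function(frame, band_step = NULL, contrast_min = 0.2) {
  stopifnot(is.matrix(frame))
  n_slit <- nrow(frame); n_spec <- ncol(frame)
  if (is.null(band_step)) band_step <- max(1L, n_spec %/% 100L)
  bands <- seq(1L, n_spec, by = band_step)
  amp <- apply(frame[, bands, drop = FALSE], 2L,
               function(p) diff(stats::quantile(p, c(0.05, 0.95))))
  keep <- amp >= contrast_min * max(amp)
  n_skipped <- sum(!keep)
  bands <- bands[keep]
  if (!length(bands)) stop("no band has usable contrast", call. = FALSE)
  ref_band <- bands[which.min(abs(bands - stats::median(bands)))]
  ref_edges <- half_crossings(frame[, ref_band])
  if (length(ref_edges) < 2L)
    stop("fewer than 2 high-contrast edges along the slit axis", call. = FALSE)
  shifts <- purrr::map_dfr(bands, function(b) {
    ed <- half_crossings(frame[, b])
    purrr::map_dfr(seq_along(ref_edges), function(k) {
      d <- abs(ed - ref_edges[k])
      if (!length(d) || min(d) > 10) return(NULL)
      tibble::tibble(band = b, edge = k, edge_pos_px = ref_edges[k],
                     shift_px = ed[which.min(d)] - ref_edges[k])
    })
  })
  central <- abs(shifts$edge_pos_px - (n_slit + 1) / 2) <= n_slit / 4
  structure(list(shifts = shifts,
                 max_shift_px = max(abs(shifts$shift_px)),
                 central_half_max_px = if (any(central))
                   max(abs(shifts$shift_px[central])) else NA_real_,
                 n_skipped_bands = n_skipped, ref_band = ref_band),
            class = "keystone_report")
}

#' @export
print.keystone_report <- function(x, ...) {
  cat(sprintf("<keystone_report> max |shift| = %.2f px (central half %.2f px), %d bands skipped\n",
              x$max_shift_px, x$central_half_max_px, x$n_skipped_bands))
  invisible(x)
}

#' Spatial homogeneity of the illumination along the slit
#'
#' Spectrally integrated intensity per slit pixel of a uniform-slab scene,
#' normalised to its maximum, compared against a reference relative
#' illumination curve (e.g. the objective maker's curve): peak-position
#' offset, maximum relative deviation, and the normalised first moment about
#' the slit centre (skew). Invariant to global exposure scaling.
#'
#' @param cube A [hypercube()] (a stack of frames is averaged).
#' @param reference_curve Data frame `(slit_px, relative_illumination)` of
#'   length equal to the slit extent, or a bare numeric vector.
#' @return A list: `profile` tibble (`slit_px`, `intensity`, `reference`,
#'   `relative_deviation`), `max_relative_deviation`,
#'   `peak_offset_px`, `skew`.
#' @export
homogeneity <- function(cube, reference_curve) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.data.frame(reference_curve))
    reference_curve <- reference_curve$relative_illumination
  m <- scan_average(cube)
  intensity <- rowSums(m)
  n <- length(intensity)
  if (length(reference_curve) != n)
    stop(sprintf("reference curve length %d != slit extent %d",
                 length(reference_curve), n), call. = FALSE)
  obs <- intensity / max(intensity)
  ref <- reference_curve / max(reference_curve)
  # broad, flat-topped profiles: centre of mass of the region above 90% of
  # the maximum localises the peak far better than a 3-point parabola
  peak_sub <- function(v) refine_centroid_com(v, which.max(v), frac = 0.9,
                                              search = length(v)) + 1
  dev <- (obs - ref) / ref
  u <- seq_len(n) - (n + 1) / 2
  list(profile = tibble::tibble(slit_px = seq_len(n), intensity = obs,
                                reference = ref, relative_deviation = dev),
       max_relative_deviation = max(abs(dev)),
       peak_offset_px = peak_sub(obs) - peak_sub(ref),
       skew = sum(u * obs) / sum(obs) / (n / 2))
}

#' Temporal stability of the illumination from a time series of white refs
#'
#' For each illumination peak and time point: wavelength (pixel) shift and
#' intensity ratio relative to the first measurement. The warm-up time is
#' estimated from a single-exponential fit
#' `I(t) = I_inf + (I0 - I_inf) exp(-t/tau)` to the most-drifting peak's
#' intensity, as the earliest time at which the predicted relative change
#' over the following 10 minutes drops below 1%.
#'
#' @param cubes List of [hypercube()]s (white references).
#' @param times_min Numeric vector of acquisition times (minutes, strictly
#'   increasing, length >= 3).
#' @param model Optional [dispersion_model()] for nm conversion of shifts.
#' @param min_prominence,min_sep_px Peak detection parameters.
#' @return An object of class `stability_report`: `table` tibble
#'   (`t_min`, `peak`, `center_px`, `shift_px`, `shift_nm`,
#'   `intensity_ratio`), `warmup_min`, `tau_min`, and the fitted `i_inf`.
#' @export
temporal_stability <- function(cubes, times_min, model = NULL,
                               min_prominence = 0.05, min_sep_px = 20) {
  stopifnot(length(cubes) == length(times_min), length(cubes) >= 3L)
  if (any(diff(times_min) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  specs <- lapply(cubes, function(cb) {
    m <- scan_average(cb)
    colMeans(m)    # slit-averaged spectrum
  })
  ref <- detect_peaks(specs[[1]], min_prominence, min_sep_px)
  if (nrow(ref) < 1L) stop("no illumination peaks found", call. = FALSE)
  peak_state <- function(spec, p) {
    # centre-of-mass centroid (broad LED peaks) and local peak height
    c0 <- refine_centroid_com(spec, ref$pixel[p] + 1L, frac = 0.7,
                              search = min_sep_px)
    i <- max(2L, min(length(spec) - 1L, round(c0) + 1L))
    base <- stats::quantile(spec, 0.05, names = FALSE)
    c(centroid = c0, intensity = max(spec[(i - 1L):(i + 1L)]) - base)
  }
  ref_state <- vapply(seq_len(nrow(ref)), function(p)
    peak_state(specs[[1]], p), numeric(2))
  tab <- purrr::map_dfr(seq_along(specs), function(i) {
    purrr::map_dfr(seq_len(nrow(ref)), function(p) {
      st <- peak_state(specs[[i]], p)
      dpx <- st["centroid"] - ref_state["centroid", p]
      tibble::tibble(
        t_min = times_min[i], peak = p,
        center_px = ref_state["centroid", p],
        shift_px = unname(dpx),
        shift_nm = if (is.null(model)) NA_real_ else
          unname(dpx) * local_dispersion(model, ref_state["centroid", p]),
        intensity_ratio = unname(st["intensity"] / ref_state["intensity", p]))
    })
  })
  # warm-up from the peak with the largest total intensity change
  drift_size <- tapply(tab$intensity_ratio, tab$peak,
                       function(r) max(r) - min(r))
  p_star <- as.integer(names(which.max(drift_size)))
  sub <- tab[tab$peak == p_star, ]
  fit <- fit_warmup_exponential(sub$t_min, sub$intensity_ratio)
  structure(list(table = tab, warmup_min = fit$warmup_min,
                 tau_min = fit$tau_min, i_inf = fit$i_inf, peak = p_star),
            class = "stability_report")
}

# Single-exponential fit I(t) = i_inf + (i0 - i_inf) exp(-t/tau) by
# profiled least squares over tau; warm-up = first t with
# |I(t+10) - I(t)| / I(t) < 1%.
fit_warmup_exponential <- function(t, i) {
  taus <- exp(seq(log(0.5), log(120), length.out = 400))
  best <- NULL; best_rss <- Inf
  for (tau in taus) {
    X <- cbind(1, exp(-t / tau))
    f <- stats::lm.fit(X, i)
    rss <- sum(f$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best <- list(tau = tau, b = f$coefficients) }
  }
  i_inf <- best$b[1]; amp <- best$b[2]; tau <- best$tau
  pred <- function(tt) i_inf + amp * exp(-tt / tau)
  tt <- seq(0, 240, by = 0.1)
  rel <- abs(pred(tt + 10) - pred(tt)) / pmax(pred(tt), 1e-9)
  idx <- which(rel < 0.01)
  warmup <- if (length(idx)) tt[idx[1]] else NA_real_
  list(tau_min = tau, i_inf = unname(i_inf), warmup_min = warmup)
}

#' Wavelength consistency between in-focus and displaced spectra
#'
#' Matches the emission peaks of two spectra sharing a spectral axis and
#' reports per-peak centroid wavelength differences. The check passes when
#' all matched deltas stay below the system spectral resolution.
#'
#' @param spectrum_focus,spectrum_displaced Counts per spectral pixel.
#' @param model [dispersion_model()] used for the nm conversion.
#' @param resolution_nm Pass threshold (default 2.9 nm).
#' @param min_prominence,min_sep_px Peak detection parameters.
#' @return A list: `deltas` tibble (`peak`, `center_px`, `delta_px`,
#'   `delta_nm`), `pass`, `partial` (TRUE when some peaks were unmatched),
#'   `n_unmatched`.
#' @export
focus_consistency <- function(spectrum_focus, spectrum_displaced, model,
                              resolution_nm = 2.9,
                              min_prominence = 0.05, min_sep_px = 20) {
  a <- detect_peaks(spectrum_focus, min_prominence, min_sep_px)
  b <- detect_peaks(spectrum_displaced, min_prominence, min_sep_px)
  if (nrow(a) < 3L)
    stop("fewer than 3 peaks in the in-focus spectrum", call. = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(a)), function(p) {
    d <- abs(b$centroid_px - a$centroid_px[p])
    if (!length(d) || min(d) > min_sep_px) return(NULL)
    j <- which.min(d)
    dpx <- b$centroid_px[j] - a$centroid_px[p]
    tibble::tibble(peak = p, center_px = a$centroid_px[p], delta_px = dpx,
                   delta_nm = dpx * local_dispersion(model, a$centroid_px[p]))
  })
  n_unmatched <- nrow(a) - nrow(rows)
  list(deltas = rows,
       pass = nrow(rows) >= 3L && all(abs(rows$delta_nm) < resolution_nm),
       partial = n_unmatched > 0L, n_unmatched = n_unmatched)
}
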