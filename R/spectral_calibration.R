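#' Detect emission peaks in a spectrum with sub-pixel centroids
#'
#' Finds local maxima whose height above the spectrum baseline exceeds
#' `min_prominence` times the full spectrum amplitude, merges maxima closer
#' than `min_sep_px` (keeping the stronger, so a blended pair is never
#' silently split), and refines each surviving maximum with a 3-point
#' log-parabolic (Gaussian) interpolation. Centroids are 0-based fractional
#' spectral pixels, matching the dispersion-model convention.
#'
#' @param spectrum Numeric vector of counts per spectral pixel (length >= 5).
#' @param min_prominence Detection threshold as a fraction of the spectrum
#'   amplitude, in `(0, 1)`.
#' @param min_sep_px Minimum separation between reported peaks.
#' @return Tibble with columns `centroid_px` (0-based), `intensity`
#'   (baseline-subtracted), `pixel` (discrete 0-based maximum), sorted by
#'   pixel. A flat spectrum yields zero rows.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05, min_sep_px = 5) {
  stopifnot(length(spectrum) >= 5L, min_prominence > 0, min_prominence < 1)
  v <- as.numeric(spectrum)
  base <- stats::quantile(v, 0.05, names = FALSE)
  amp <- max(v) - base
  empty <- tibble::tibble(centroid_px = numeric(0), intensity = numeric(0),
                          pixel = numeric(0))
  if (amp <= 0) return(empty)
  n <- length(v)
  i <- 2:(n - 1)
  idx <- i[v[i] > v[i - 1] & v[i] >= v[i + 1]]
  if (!length(idx)) return(empty)
  # topographic prominence: peak height above the higher of the two key
  # saddles (minima towards the nearest higher point on each side), so noise
  # ripples riding on a bright broad band are not peaks of their own
  prominence <- vapply(idx, function(k) {
    lo <- k; while (lo > 1L && v[lo - 1L] <= v[k]) lo <- lo - 1L
    left_min <- min(v[max(1L, lo - 1L):k])
    hi <- k; while (hi < n && v[hi + 1L] <= v[k]) hi <- hi + 1L
    right_min <- min(v[k:min(n, hi + 1L)])
    v[k] - max(left_min, right_min)
  }, numeric(1))
  idx <- idx[prominence >= min_prominence * amp]
  if (!length(idx)) return(empty)
  # merge maxima closer than min_sep_px, strongest first
  ord <- idx[order(v[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (k in ord)
    if (!length(kept) || min(abs(kept - k)) >= min_sep_px)
      kept <- c(kept, k)
  kept <- sort(kept)
  off <- vapply(kept, function(k) log_parabolic_offset(v - base + 1e-12, k),
                numeric(1))
  tibble::tibble(centroid_px = kept - 1 + off,
                 intensity = v[kept] - base,
                 pixel = kept - 1)
}

#' Iteratively assign detected peaks to reference lamp lines
#'
#' Stage 1 (when no coarse model is supplied): for each unambiguous anchor
#' species (mercury, hydrogen), the brightest few peaks are selected by
#' intensity rank and paired with the brightest tabulated lines; because the
#' dispersion is monotone, both sides are then sorted by position before
#' pairing, and a provisional cubic is fitted with iterative trimming of the
#' worst residual (a blend or a swapped rank shows up as a gross outlier).
#' Stage 2: every detected peak from every lamp is mapped to a predicted
#' wavelength through the provisional (or supplied) model and matched to the
#' nearest reference line of its species within `tol_nm`; the fit is then
#' refined and the matching repeated (the closely spaced neon and argon
#' lines only resolve once the estimate is good). Peaks with no candidate,
#' with more than one candidate in the window, or whose reference has a
#' same-species neighbour closer than `min_line_sep_nm` (a blend at the
#' instrumental resolution) are dropped, with a message giving the count.
#'
#' @param peaks Named list of peak tibbles from [detect_peaks()], one per
#'   lamp species (names as in [lamp_line_table()]).
#' @param references Reference table (default [lamp_line_table()]).
#' @param coarse Optional [dispersion_model()] replacing stage 1.
#' @param tol_nm Matching window half-width (default 1.5 nm, about 5 px).
#' @param min_line_sep_nm Reference lines closer than this to a same-species
#'   neighbour are treated as blended and excluded (default 3.5 nm, about
#'   1.2 x the instrumental FWHM).
#' @param stage1_top Named vector: how many of the brightest peaks/lines to
#'   rank-match per unambiguous species in stage 1.
#' @return Tibble of line matches: `species`, `wavelength_nm`,
#'   `centroid_px`, `intensity`.
#' @export
assign_lines <- function(peaks, references = lamp_line_table(), coarse = NULL,
                         tol_nm = 1.5, min_line_sep_nm = 3.5,
                         stage1_top = c("Hg/Ar" = 5, "H" = 3)) {
  stopifnot(is.list(peaks), !is.null(names(peaks)))
  if (is.null(coarse)) {
    anchors <- intersect(names(stage1_top), names(peaks))
    if (!length(anchors))
      stop("without a coarse model, Hg/Ar or H lamps are required",
           call. = FALSE)
    prov <- list()
    for (sp in anchors) {
      k <- stage1_top[[sp]]
      pk <- peaks[[sp]]
      ref <- references[references$species == sp, ]
      k <- min(k, nrow(pk), nrow(ref))
      if (k < 1L) next
      pk_top <- pk[order(pk$intensity, decreasing = TRUE)[seq_len(k)], ]
      ref_top <- ref[order(ref$relative_intensity,
                           decreasing = TRUE)[seq_len(k)], ]
      # monotone dispersion: the k brightest peaks, in pixel order, pair
      # with the k brightest tabulated lines in wavelength order
      prov[[sp]] <- tibble::tibble(
        centroid_px = sort(pk_top$centroid_px),
        wavelength_nm = sort(ref_top$wavelength_air_nm))
    }
    prov <- dplyr::bind_rows(prov)
    if (nrow(prov) < 5L)
      stop("insufficient anchor lines for the provisional fit", call. = FALSE)
    # trim gross outliers (blends, swapped ranks) from the anchor pairs
    repeat {
      fit <- fit_cubic_coef(prov$centroid_px, prov$wavelength_nm)
      res <- prov$wavelength_nm - fit$fitted
      if (max(abs(res)) <= 3 || nrow(prov) <= 5L) break
      prov <- prov[-which.max(abs(res)), ]
    }
    predict_nm <- function(x) poly_eval(fit$coef, x)
  } else {
    predict_nm <- function(x) wavelength_of_pixel(coarse, x)
  }

  match_pass <- function(predict_nm) {
    dropped <- 0L
    out <- list()
    for (sp in names(peaks)) {
      pk <- peaks[[sp]]
      if (!nrow(pk)) next
      ref <- references[references$species == sp, ]
      ref_wl <- ref$wavelength_air_nm
      sep_ok <- if (length(ref_wl) > 1L) {
        d <- abs(outer(ref_wl, ref_wl, `-`)); diag(d) <- Inf
        apply(d, 1L, min) >= min_line_sep_nm
      } else TRUE
      pred <- predict_nm(pk$centroid_px)
      for (j in seq_len(nrow(pk))) {
        dists <- abs(ref_wl - pred[j])
        cand <- which(dists <= tol_nm)
        if (length(cand) != 1L || !sep_ok[cand]) { dropped <- dropped + 1L; next }
        out[[length(out) + 1L]] <- tibble::tibble(
          species = sp, wavelength_nm = ref_wl[cand],
          centroid_px = pk$centroid_px[j], intensity = pk$intensity[j])
      }
    }
    list(matches = dplyr::bind_rows(out), dropped = dropped)
  }

  # iterate: each refit extends the trustworthy range of the prediction
  pass <- match_pass(predict_nm)
  for (it in 1:2) {
    if (nrow(pass$matches) >= 5L) {
      f <- fit_cubic_coef(pass$matches$centroid_px, pass$matches$wavelength_nm)
      pass <- match_pass(function(x) poly_eval(f$coef, x))
    }
  }
  matches <- pass$matches
  if (pass$dropped > 0L)
    message(sprintf("assign_lines: dropped %d unmatched or ambiguous peaks",
                    pass$dropped))
  if (nrow(matches) < 4L)
    stop("fewer than 4 line matches; the cubic dispersion is underdetermined",
         call. = FALSE)
  dplyr::arrange(matches, .data$centroid_px)
}

poly_eval <- function(coef, x) coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3

# Bare conditioned cubic LS: raw-pixel coefficients and fitted values, no
# model object (monotonicity is not enforced here; provisional fits on few
# anchor points may wiggle outside the anchored range).
fit_cubic_coef <- function(x, y) {
  mu <- mean(x); s <- stats::sd(x)
  z <- (x - mu) / s
  X <- cbind(1, z, z^2, z^3)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  M <- matrix(0, 4, 4)
  for (k in 0:3)
    for (j in 0:k)
      M[j + 1, k + 1] <- choose(k, j) * (-mu)^(k - j) / s^k
  list(coef = as.vector(M %*% beta), fitted = as.vector(X %*% beta))
}

# Cubic least squares of wavelength on pixel, fitted on a centred/scaled
# pixel coordinate for conditioning and mapped back to raw-pixel
# coefficients (with covariance).
fit_cubic_ls <- function(x, y) {
  mu <- mean(x); s <- stats::sd(x)
  if (s == 0) stop("conditioning error: all centroids identical", call. = FALSE)
  z <- (x - mu) / s
  X <- cbind(1, z, z^2, z^3)
  cond <- kappa(X, exact = TRUE)
  if (cond > 1e10)
    stop(sprintf("conditioning error: design condition number %.3g", cond),
         call. = FALSE)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  dof <- length(y) - 4L
  sigma2 <- if (dof > 0) sum(fit$residuals^2) / dof else 0
  XtXinv <- chol2inv(chol(crossprod(X)))
  cov_beta <- sigma2 * XtXinv
  # map coefficients of z^k to coefficients of x^j via z = (x - mu)/s
  M <- matrix(0, 4, 4)
  for (k in 0:3) {
    # ((x - mu)/s)^k = sum_j C(k,j) x^j (-mu)^(k-j) / s^k
    for (j in 0:k)
      M[j + 1, k + 1] <- choose(k, j) * (-mu)^(k - j) / s^k
  }
  coef_x <- as.vector(M %*% beta)
  cov_x <- M %*% cov_beta %*% t(M)
  cov_x <- (cov_x + t(cov_x)) / 2
  model <- dispersion_model(coef_x[1], coef_x[2], coef_x[3], coef_x[4],
                            covariance = cov_x,
                            n_pixels = max(2048, ceiling(max(x)) + 1))
  list(model = model, fitted = as.vector(X %*% beta), sigma2 = sigma2)
}

#' Fit the cubic dispersion to assigned line matches
#'
#' Ordinary least squares of reference wavelength on `{1, x, x^2, x^3}` of
#' the detected centroid (computed on a centred pixel coordinate for
#' numerical conditioning and mapped back). Residuals are
#' `lambda_ref - lambda_fit` per line.
#'
#' @param matches Tibble from [assign_lines()] (columns `wavelength_nm`,
#'   `centroid_px`; `species` optional).
#' @param n_pixels Detector spectral extent used for the span check.
#' @return An object of class `calibration_fit` with elements `model`
#'   ([dispersion_model()] with covariance), `matches` (with a `residual_nm`
#'   column), `max_abs_residual_nm`, `n_lines`.
#' @export
fit_dispersion <- function(matches, n_pixels = 2048L) {
  stopifnot(all(c("wavelength_nm", "centroid_px") %in% names(matches)))
  if (nrow(matches) < 4L)
    stop("at least 4 matches are required for a cubic fit", call. = FALSE)
  span <- diff(range(matches$centroid_px))
  if (span < n_pixels / 3)
    stop(sprintf("matches span %.0f px, less than 1/3 of the %d-px detector",
                 span, n_pixels), call. = FALSE)
  fit <- fit_cubic_ls(matches$centroid_px, matches$wavelength_nm)
  res <- matches$wavelength_nm - fit$fitted
  matches <- dplyr::mutate(matches, fitted_nm = fit$fitted, residual_nm = res)
  structure(list(model = fit$model, matches = matches,
                 residuals_nm = res,
                 max_abs_residual_nm = max(abs(res)),
                 n_lines = nrow(matches),
                 sigma_nm = sqrt(fit$sigma2)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %d lines, max |residual| = %.3f nm\n",
              x$n_lines, x$max_abs_residual_nm))
  print(x$model)
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) tidy(x$model)

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(n_lines = x$n_lines,
                 max_abs_residual_nm = x$max_abs_residual_nm,
                 sigma_nm = x$sigma_nm)
}

#' Measure the FWHM of a spectral line
#'
#' Locates the half-maximum crossings on both flanks of the peak by linear
#' interpolation (no symmetric model is assumed, so asymmetric lines are
#' handled faithfully) and converts the width to nm through the local
#' dispersion `b + 2 c x + 3 d x^2` when a model is given.
#'
#' @param spectrum Counts per spectral pixel.
#' @param centroid_px Peak centroid (0-based), e.g. from [detect_peaks()].
#' @param model Optional [dispersion_model()] for the nm conversion.
#' @return A list: `fwhm_px`, `fwhm_nm` (NA without a model), `flag`
#'   (`"ok"`, `"one-sided"` when only one flank reaches half max, or
#'   `"under-resolved"` for a single hot pixel).
#' @export
measure_fwhm <- function(spectrum, centroid_px, model = NULL) {
  v <- as.numeric(spectrum)
  base <- stats::quantile(v, 0.05, names = FALSE)
  i0 <- round(centroid_px) + 1L
  stopifnot(i0 >= 1L, i0 <= length(v))
  half <- base + (v[i0] - base) / 2
  n <- length(v)
  left <- NA_real_; right <- NA_real_
  j <- i0
  while (j > 1L && v[j - 1L] > half) j <- j - 1L
  if (j > 1L)
    left <- (j - 1L) + (half - v[j - 1L]) / (v[j] - v[j - 1L]) - 1  # 0-based
  j <- i0
  while (j < n && v[j + 1L] > half) j <- j + 1L
  if (j < n)
    right <- (j - 1L) + (half - v[j]) / (v[j + 1L] - v[j]) - 1 + 1
  flag <- "ok"
  if (is.na(left) && is.na(right))
    stop("no flank reaches half maximum", call. = FALSE)
  if (is.na(left)) { left <- centroid_px - (right - centroid_px); flag <- "one-sided" }
  if (is.na(right)) { right <- centroid_px + (centroid_px - left); flag <- "one-sided" }
  fwhm_px <- right - left
  if (fwhm_px <= 1) flag <- "under-resolved"
  fwhm_nm <- if (is.null(model)) NA_real_
             else fwhm_px * local_dispersion(model, centroid_px)
  list(fwhm_px = fwhm_px, fwhm_nm = fwhm_nm, flag = flag)
}
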