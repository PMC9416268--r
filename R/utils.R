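# Small numeric helpers shared across modules.

# Centered running average with window truncation at the edges.
running_mean <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# 1-D Gaussian blur with reflected edges; fwhm in samples.
gaussian_blur_1d <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - (1:half) + 1L, 1L)])
  as.numeric(stats::filter(pad, k, sides = 2))[(half + 1L):(half + n)]
}

# Blur matrix rows (margin = 1) or columns (margin = 2); dims preserved
# even for single-row/column inputs, where apply() would simplify.
gaussian_blur_mat <- function(m, fwhm, margin) {
  if (fwhm <= 0) return(m)
  out <- if (margin == 1L) t(apply(m, 1L, gaussian_blur_1d, fwhm = fwhm))
         else apply(m, 2L, gaussian_blur_1d, fwhm = fwhm)
  matrix(out, nrow(m), ncol(m))
}

# Sub-pixel 50%-amplitude crossings of a profile. Amplitude bounds from the
# 5th/95th percentiles; returns fractional positions (1-based index units).
half_crossings <- function(profile) {
  q <- stats::quantile(profile, c(0.05, 0.95), names = FALSE)
  if (diff(q) <= 0) return(numeric(0))
  mid <- mean(q)
  s <- profile - mid
  idx <- which(s[-1] * s[-length(s)] < 0)
  idx + s[idx] / (s[idx] - s[idx + 1L])
}

# Amount of "dark" in [0, t) for a square wave of period p whose dark half
# occupies [p/2, p) of every period (phase 0 at 0).
square_wave_dark_integral <- function(t, period) {
  k <- floor(t / period)
  r <- t - k * period
  k * (period / 2) + pmax(0, r - period / 2)
}

# Per-pixel dark coverage of a square wave over n pixels of width `pitch`,
# pattern shifted by `phase` (mm). Exact area averaging.
square_wave_coverage <- function(n, pitch, period, phase = 0) {
  edges <- (0:n) * pitch - phase
  shift <- (ceiling(max(0, -min(edges)) / period) + 1) * period  # whole periods
  f <- square_wave_dark_integral(edges + shift, period)
  diff(f) / pitch
}

# Per-pixel coverage of the interval [lo, hi) (same units as pitch).
interval_coverage <- function(n, pitch, lo, hi) {
  p0 <- (0:(n - 1)) * pitch
  p1 <- p0 + pitch
  pmax(0, pmin(hi, p1) - pmax(lo, p0)) / pitch
}

# Coerce a reflectance/transmittance description to a function of nm:
# scalar, data.frame(wavelength_nm, value), or function.
as_spectrum <- function(x) {
  if (is.function(x)) return(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("wavelength_nm", "value") %in% names(x)))
    return(stats::approxfun(x$wavelength_nm, x$value, rule = 2))
  }
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(lambda) rep_len(x, length(lambda)))
  }
  stop("cannot interpret spectrum specification", call. = FALSE)
}

# Local quadratic (Savitzky-Golay-style) smoother with the same window
# everywhere: at the edges the window is one-sided but the quadratic is
# still fit exactly, so a parabolic profile passes through unbiased --
# which a truncated running mean does not do at the profile's extremum.
local_quad_smooth <- function(y, window) {
  n <- length(y)
  if (window <= 3L || n < 5L) return(y)
  half <- window %/% 2L
  out <- numeric(n)
  interior <- (half + 1L):(n - half)
  if (length(interior) > 0L && interior[1] <= interior[length(interior)]) {
    t <- -half:half
    X <- cbind(1, t, t^2)
    w <- solve(crossprod(X), t(X))[1L, ]          # evaluation at t = 0
    sm <- stats::filter(y, rev(w), sides = 2)
    out[interior] <- sm[interior]
  }
  for (i in c(seq_len(min(half, n)), seq.int(max(1L, n - half + 1L), n))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    t <- (lo:hi) - i
    X <- cbind(1, t, t^2)
    out[i] <- solve(crossprod(X), crossprod(X, y[lo:hi]))[1L]
  }
  out
}

# Centre-of-mass sub-pixel refinement for broad peaks: centroid of the
# contiguous region around the local maximum `i0` where the
# baseline-subtracted signal exceeds `frac` of the peak. Far more robust
# than a 3-point parabola when the peak spans tens of pixels (LED bands).
refine_centroid_com <- function(v, i0, frac = 0.7, search = 10L) {
  n <- length(v)
  lo <- max(1L, i0 - search); hi <- min(n, i0 + search)
  i0 <- (lo:hi)[which.max(v[lo:hi])]
  base <- stats::quantile(v, 0.05, names = FALSE)
  thr <- base + frac * (v[i0] - base)
  # the window never extends past `search` from the maximum, so it cannot
  # spill across a shallow saddle into a stronger neighbouring peak
  l <- i0; while (l > max(1L, i0 - search) && v[l - 1L] >= thr) l <- l - 1L
  r <- i0; while (r < min(n, i0 + search) && v[r + 1L] >= thr) r <- r + 1L
  w <- v[l:r] - thr
  w <- pmax(w, 0)
  sum((l:r) * w) / sum(w) - 1   # 0-based
}

# Parabolic (3-point, log-domain) sub-pixel peak refinement around index i.
log_parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  l <- log(pmax(y[(i - 1L):(i + 1L)], .Machine$double.xmin))
  den <- l[1] - 2 * l[2] + l[3]
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (l[1] - l[3]) / den
  max(-0.5, min(0.5, off))
}
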