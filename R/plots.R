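#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   labs facet_wrap
NULL

#' Residual plot for a dispersion calibration fit
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot of residuals (nm) against reference wavelength.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot(object$matches,
         aes(x = .data$wavelength_nm, y = .data$residual_nm,
             colour = .data$species)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_point() +
    labs(x = "reference wavelength (nm)", y = "residual (nm)",
         title = sprintf("Cubic dispersion fit: %d lines, max |residual| %.3f nm",
                         object$n_lines, object$max_abs_residual_nm))
}

#' Smile offset profiles along the slit
#'
#' @param object A `smile_report`.
#' @param ... Unused.
#' @return A ggplot of smoothed per-peak spectral offsets against slit pixel.
#' @export
autoplot.smile_report <- function(object, ...) {
  ggplot(object$profiles,
         aes(x = .data$slit_px, y = .data$offset_px,
             group = .data$peak, colour = factor(round(.data$peak_center_px)))) +
    geom_line() +
    labs(x = "slit pixel", y = "spectral offset (px)",
         colour = "peak (px)",
         title = sprintf("Spectral smile: max |offset| %.2f px",
                         object$max_offset_px))
}

#' Keystone edge shifts across the spectral range
#'
#' @param object A `keystone_report`.
#' @param ... Unused.
#' @return A ggplot of per-edge slit shifts against spectral band.
#' @export
autoplot.keystone_report <- function(object, ...) {
  ggplot(object$shifts,
         aes(x = .data$band, y = .data$shift_px,
             group = .data$edge, colour = factor(round(.data$edge_pos_px)))) +
    geom_line() +
    labs(x = "spectral band", y = "edge shift (px)", colour = "edge (px)",
         title = sprintf("Keystone: max |shift| %.2f px", object$max_shift_px))
}

#' Illumination stability time series
#'
#' @param object A `stability_report`.
#' @param ... Unused.
#' @return A ggplot of per-peak intensity ratios against time.
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot(object$table,
         aes(x = .data$t_min, y = .data$intensity_ratio,
             group = .data$peak, colour = factor(round(.data$center_px)))) +
    geom_line() + geom_point() +
    labs(x = "time since switch-on (min)", y = "intensity ratio",
         colour = "peak (px)",
         title = sprintf("Illumination warm-up: %.0f min", object$warmup_min))
}

#' @export
tidy.stability_report <- function(x, ...) x$table

#' @export
tidy.smile_report <- function(x, ...) x$profiles

#' @export
glance.smile_report <- function(x, ...) {
  tibble::tibble(max_offset_px = x$max_offset_px,
                 max_offset_nm = x$max_offset_nm,
                 below_pixel = x$below_pixel)
}

#' @export
glance.keystone_report <- function(x, ...) {
  tibble::tibble(max_shift_px = x$max_shift_px,
                 central_half_max_px = x$central_half_max_px,
                 n_skipped_bands = x$n_skipped_bands)
}
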