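# broom-style methods for registration results.

#' Tidy an ICR registration
#'
#' One row per registration with every scalar descriptor plus the axis
#' report coordinates, ready for row-binding across cases.
#'
#' @param x An `icr_registration` from [register_icr()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.icr_registration <- function(x, ...) {
  tibble(
    alpha2 = x$alpha2,
    slide = x$slide,
    d_axis = x$d_axis,
    angular_deviation = x$angular_deviation,
    ecd_ratio = x$ecd_ratio,
    translation_magnitude = x$translation_magnitude,
    rms_after = x$rms_after,
    fit_rms = x$fit_rms,
    report_x = x$report_coords[["x"]],
    report_y = x$report_coords[["y"]],
    report_z = x$report_coords[["z"]],
    exec_time = x$exec_time
  )
}

#' Glance at an ICR registration
#'
#' @param x An `icr_registration`.
#' @param ... Unused.
#' @return A one-row tibble with the quality summary: recovered angle,
#'   axis displacement, substitution residual and fit residual.
#' @export
glance.icr_registration <- function(x, ...) {
  tibble(alpha2 = x$alpha2, d_axis = x$d_axis,
         angular_deviation = x$angular_deviation,
         rms_after = x$rms_after, fit_rms = x$fit_rms)
}
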