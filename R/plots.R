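# ggplot2 views of the three result types.

#' Plot EcD ratios against the rotation angle
#'
#' Registered EcD ratios of a transition run, with the exact relation
#' `1/(2 sin(alpha/2))` drawn underneath. On a noise-free run the points
#' sit on the curve regardless of translation magnitude or direction.
#'
#' @param object An `icr_transition_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icr_transition_result <- function(object, ...) {
  ok <- dplyr::filter(as_tibble(object), .data$ok)
  grid <- tibble(alpha1 = seq(min(ok$alpha1), max(ok$alpha1),
                              length.out = 200))
  grid$ecd <- ecd_analytic(grid$alpha1)
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$alpha1, y = .data$ecd_ratio)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$ecd),
                       colour = "grey55") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$direction),
                        alpha = 0.7) +
    ggplot2::labs(x = "rotation angle α1 (deg)",
                  y = "EcD ratio (mm axis shift per mm translation)",
                  colour = "tₑ direction",
                  title = "Error-caused displacement of the registered ICR",
                  subtitle = "line: 1 / (2 sin(α1/2))") +
    ggplot2::theme_minimal()
}

#' Plot AEcFE tolerance by error type
#'
#' Mean axis-error tolerance (AEcFE, mm of axis error per mm of residual
#' rms) per group, split by error type and group path. Larger is more
#' tolerant; parallel errors far from the body are the benign ones.
#'
#' @param object An `icr_axis_error_result` or `icr_axis_error_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icr_axis_error_result <- function(object, ...) {
  autoplot.icr_axis_error_summary(summarize_axis_error(object), ...)
}

#' @rdname autoplot.icr_axis_error_result
#' @export
autoplot.icr_axis_error_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$group_offset, y = .data$mean_aecfe,
                               colour = .data$error_type)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_grid(.data$series ~ .data$path, scales = "free_x") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "group offset along its path (mm or deg)",
                  y = "mean AEcFE (mm axis error per mm rms)",
                  colour = "error type",
                  title = "Axis-error tolerance by error type and group position") +
    ggplot2::theme_minimal()
}

#' Plot a fitted EcD curve over its data
#'
#' @param object An `ecd_fit` from [fit_ecd_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecd_fit <- function(object, ...) {
  grid <- tibble(alpha = seq(min(object$data$alpha), max(object$data$alpha),
                             length.out = 200))
  grid$ecd <- ecd_curve(grid$alpha, object$params)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$alpha, y = .data$ecd)) +
    ggplot2::geom_line(data = grid, colour = "grey55") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rotation angle (deg)", y = "EcD ratio",
                  title = sprintf("EcD(α) = %.6g/α^%.6g + %.6g",
                                  object$params$a, object$params$b,
                                  object$params$c)) +
    ggplot2::theme_minimal()
}
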