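# Closed-form kinematics of the ICR displacement caused by a translational
# component superimposed on a rotation. Throughout, alpha is the rotation
# angle in degrees and the translation t_e is perpendicular to the rotation
# axis; angles beyond 180 degrees are re-expressed as opposite-sense
# rotations of 360 - alpha.

.normalize_alpha <- function(alpha, tol = 1e-9) {
  if (length(alpha) != 1L || !is.finite(alpha)) {
    abort("`alpha1` must be a single finite angle in degrees.",
          class = "icrlab_error_parameter")
  }
  a <- alpha %% 360
  if (min(a, 360 - a) < tol) {
    abort("A rotation by a multiple of 360 degrees is the identity: the ICR is undefined.",
          class = "icrlab_error_identity_rotation")
  }
  sense <- 1
  if (a > 180) {
    a <- 360 - a
    sense <- -1
  }
  list(alpha = a, sense = sense)
}

#' Length of the ICR displacement caused by a perpendicular translation
#'
#' For a rotation by `alpha1` degrees combined with a translation of
#' magnitude `te_magnitude` perpendicular to the rotation axis, the
#' registered instantaneous axis is displaced from the original axis by
#' `te_magnitude / (2 sin(alpha1 / 2))` (sine law in the isosceles triangle
#' formed by the two centers and the half-translation). At
#' `alpha1 = 180` this is `te_magnitude / 2`. Vectorized over both
#' arguments.
#'
#' @param te_magnitude Translation magnitude in mm (>= 0).
#' @param alpha1 Rotation angle in degrees, not a multiple of 360.
#' @return Displacement of the registered axis in mm.
#' @examples
#' d_axis_length(1, 2)    # about 28.65 mm
#' d_axis_length(2, 180)  # 1 mm
#' @export
d_axis_length <- function(te_magnitude, alpha1) {
  if (any(!is.finite(te_magnitude)) || any(te_magnitude < 0)) {
    abort("`te_magnitude` must be finite and >= 0.",
          class = "icrlab_error_parameter")
  }
  n <- max(length(te_magnitude), length(alpha1))
  te_magnitude <- rep_len(te_magnitude, n)
  alpha1 <- rep_len(alpha1, n)
  a <- vapply(alpha1, function(x) .normalize_alpha(x)$alpha, numeric(1))
  te_magnitude / (2 * sin(.deg2rad(a) / 2))
}

#' Direction of the ICR displacement
#'
#' The registered axis is displaced from the original axis in the plane
#' perpendicular to the rotation axis, at `90 - alpha1/2` degrees from the
#' translation direction, measured in the same rotation sense as the
#' original rotation. For `alpha1 = 180` the displacement points along the
#' translation itself.
#'
#' @param te_unit Unit vector of the translation, perpendicular to the
#'   rotation axis.
#' @param alpha1 Rotation angle in degrees.
#' @param axis_direction Unit direction of the rotation axis (default: the
#'   +x hinge of the standard setup).
#' @param rotation_sense +1 for rotation by `+alpha1` about
#'   `axis_direction` (right-hand rule), -1 for the opposite sense.
#' @return Unit length-3 vector.
#' @export
d_axis_direction <- function(te_unit, alpha1, axis_direction = c(1, 0, 0),
                             rotation_sense = 1) {
  u <- .unit3(axis_direction, "axis_direction")
  te <- .unit3(te_unit, "te_unit")
  if (abs(sum(te * u)) > 1e-8) {
    abort("`te_unit` must be perpendicular to the rotation axis.",
          class = "icrlab_error_geometry")
  }
  if (!rotation_sense %in% c(-1, 1)) {
    abort("`rotation_sense` must be +1 or -1.", class = "icrlab_error_parameter")
  }
  na <- .normalize_alpha(alpha1)
  sense <- rotation_sense * na$sense
  R <- .rotation_matrix(u, sense * (90 - na$alpha / 2))
  as.numeric(R %*% te)
}

#' Predicted position of the registered instantaneous axis
#'
#' Combines [d_axis_length()] and [d_axis_direction()]: the axis about
#' which a single rotation by `alpha1` reproduces "rotate by `alpha1` about
#' `o_ocr`, then translate by `te_vector`". The prediction is exact: the
#' composed motion and the single rotation about the predicted axis agree
#' vertexwise to machine precision.
#'
#' @param o_ocr `axis3d`, the original center/axis of rotation.
#' @param te_vector Translation in mm, perpendicular to the axis.
#' @param alpha1 Rotation angle in degrees.
#' @param rotation_sense +1 or -1, the sense of the original rotation.
#' @return An `axis3d` parallel to `o_ocr`.
#' @export
predicted_icr <- function(o_ocr, te_vector, alpha1, rotation_sense = 1) {
  .check_axis(o_ocr, "o_ocr")
  te <- .vec3(te_vector, "te_vector")
  mag <- .norm3(te)
  if (mag == 0) return(o_ocr)
  dir <- d_axis_direction(te / mag, alpha1, o_ocr$direction, rotation_sense)
  len <- d_axis_length(mag, alpha1)
  # keep the input orientation: the caller's rotation sense refers to it
  axis3d(o_ocr$anchor + len * dir, o_ocr$direction, canonical = FALSE)
}

#' Analytic error-caused displacement (EcD) ratio
#'
#' `EcD = d_axis / |t_e| = 1 / (2 sin(alpha1/2))`: how many millimetres the
#' registered axis moves per millimetre of translational component
#' perpendicular to the axis. Strictly decreasing in the rotation angle on
#' (0, 180\]; this is why small-rotation ICR registration is so sensitive
#' to translational noise. Vectorized.
#'
#' @param alpha1 Rotation angle(s) in degrees, not multiples of 360.
#' @return Dimensionless ratio(s).
#' @examples
#' round(ecd_analytic(c(2, 4, 6)), 2)  # 28.65 14.33 9.55
#' @export
ecd_analytic <- function(alpha1) {
  d_axis_length(rep(1, length(alpha1)), alpha1)
}

#' Parameters of the empirical EcD power-law curve
#'
#' The EcD-versus-angle relation is conventionally summarized by the fitted
#' power law `EcD(alpha) = a / alpha^b + c`. The defaults are the reference
#' coefficients of that fit (the curve fitted to EcD ratios tabulated at two
#' decimals over the eight standard closure angles); [fit_ecd_curve()]
#' recovers them from such a table.
#'
#' @param a Scale coefficient (> 0). The small-angle limit of the exact
#'   relation gives `a = 180 / pi = 57.29578` with `b = 1`, `c = 0`.
#' @param b Exponent, close to 1.
#' @param c Additive offset.
#' @return An object of class `ecd_curve_params`.
#' @export
ecd_curve_params <- function(a = 57.2880981, b = 0.999893022, c = 0.00303367017) {
  if (!is.finite(a) || a <= 0) {
    abort("`a` must be positive.", class = "icrlab_error_parameter")
  }
  structure(list(a = a, b = b, c = c), class = "ecd_curve_params")
}

#' @export
print.ecd_curve_params <- function(x, ...) {
  cat(sprintf("<EcD curve> EcD(alpha) = %.10g / alpha^%.10g + %.10g\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Evaluate the empirical EcD power-law curve
#'
#' @param alpha1 Rotation angle(s) in degrees, > 0.
#' @param params An [ecd_curve_params()] object.
#' @return `a / alpha1^b + c`, vectorized over `alpha1`.
#' @export
ecd_curve <- function(alpha1, params = ecd_curve_params()) {
  if (!inherits(params, "ecd_curve_params")) {
    abort("`params` must come from `ecd_curve_params()` or `fit_ecd_curve()`.",
          class = "icrlab_error_parameter")
  }
  if (any(!is.finite(alpha1)) || any(alpha1 <= 0)) {
    abort("`alpha1` must be positive and finite.",
          class = "icrlab_error_parameter")
  }
  params$a / alpha1^params$b + params$c
}

#' Fit the EcD power-law curve to measured ratios
#'
#' Nonlinear least squares for `ecd ~ a / alpha^b + c` via
#' Levenberg-Marquardt. The three parameters are nearly degenerate when the
#' angle range is narrow (the exact relation is almost `a/alpha` there), so
#' the fit starts from the small-angle closed form `a = 180/pi, b = 1,
#' c = 0` and constrains `b` to \[0.5, 1.5\].
#'
#' @param data Data frame with the angle and ratio columns.
#' @param alpha,ecd Column names (tidy-eval) holding angles (degrees) and
#'   EcD ratios. Defaults `alpha` and `ecd`.
#' @return An object of class `ecd_fit`; its `$params` slot is an
#'   [ecd_curve_params()]. [tidy()] and [glance()] methods are provided.
#' @examples
#' tab <- tibble::tibble(alpha = c(2, 2.5, 3, 3.5, 4, 4.5, 6, 9))
#' tab$ecd <- round(ecd_analytic(tab$alpha), 2)
#' fit_ecd_curve(tab)$params
#' @export
fit_ecd_curve <- function(data, alpha = "alpha", ecd = "ecd") {
  alpha_col <- rlang::as_name(rlang::enquo(alpha))
  ecd_col <- rlang::as_name(rlang::enquo(ecd))
  if (!is.data.frame(data) || !all(c(alpha_col, ecd_col) %in% names(data))) {
    abort(sprintf("`data` must contain columns `%s` and `%s`.", alpha_col, ecd_col),
          class = "icrlab_error_parameter")
  }
  d <- data.frame(alpha = as.numeric(data[[alpha_col]]),
                  ecd = as.numeric(data[[ecd_col]]))
  d <- d[is.finite(d$alpha) & is.finite(d$ecd), , drop = FALSE]
  if (length(unique(d$alpha)) < 4L) {
    abort("At least 4 distinct angles are needed to fit the 3-parameter curve.",
          class = "icrlab_error_parameter")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ecd ~ a / alpha^b + c, data = d,
      start = list(a = 180 / pi, b = 1, c = 0),
      lower = c(a = 1e-8, b = 0.5, c = -Inf),
      upper = c(a = Inf, b = 1.5, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 1000,
                                           ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) {
      abort(paste0("EcD curve fit failed to converge: ", conditionMessage(e)),
            class = "icrlab_error_fit_failure")
    }
  )
  co <- coef(fit)
  structure(list(
    params = ecd_curve_params(co[["a"]], co[["b"]], co[["c"]]),
    fit = fit,
    data = tibble(alpha = d$alpha, ecd = d$ecd,
                  fitted = as.numeric(fitted(fit)),
                  residual = as.numeric(residuals(fit))),
    mean_abs_error = mean(abs(residuals(fit)))
  ), class = "ecd_fit")
}

#' @export
print.ecd_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("fitted to %d points; mean absolute error %.3g\n",
              nrow(x$data), x$mean_abs_error))
  invisible(x)
}

#' @importFrom stats fitted vcov
#' @export
tidy.ecd_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s),
         estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"],
         statistic = s[, "t value"],
         p.value = s[, "Pr(>|t|)"])
}

#' @export
glance.ecd_fit <- function(x, ...) {
  tibble(n = nrow(x$data),
         mean_abs_error = x$mean_abs_error,
         sigma = summary(x$fit)$sigma,
         converged = x$fit$convInfo$isConv %||% TRUE,
         iterations = x$fit$convInfo$finIter %||% NA_integer_)
}
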