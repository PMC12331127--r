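#' Proper rigid transforms
#'
#' A rigid transform maps a point `v` to `R v + t` with `R` a proper
#' (det = +1) orthonormal 3x3 rotation and `t` a translation in mm.
#' Constructors are provided for the identity, pure rotations about an
#' axis, pure translations, and general (R, t) pairs.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (checked to
#'   1e-10).
#' @param translation Numeric length-3 (mm).
#' @return An object of class `icr_rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    abort("`rotation` must be a finite 3x3 matrix.",
          class = "icrlab_error_parameter")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    abort("`rotation` must be orthonormal with determinant +1 (within 1e-10).",
          class = "icrlab_error_parameter")
  }
  structure(list(rotation = rotation, translation = .vec3(translation, "translation")),
            class = "icr_rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @rdname rigid_transform
#' @param axis An `axis3d` the rotation is taken about.
#' @param angle Rotation angle in degrees (right-hand rule about
#'   `axis$direction`).
#' @export
rt_rotation <- function(axis, angle) {
  .check_axis(axis)
  R <- .rotation_matrix(axis$direction, angle)
  rigid_transform(R, axis$anchor - R %*% axis$anchor)
}

#' @rdname rigid_transform
#' @param vector Translation vector in mm.
#' @export
rt_translation <- function(vector) {
  rigid_transform(diag(3), vector)
}

#' Screw (helical) motion transform: rotation about an axis plus a slide
#' along it
#'
#' @param axis An `axis3d`.
#' @param angle Rotation angle in degrees about `axis$direction`.
#' @param slide Signed translation along `axis$direction` in mm.
#' @return An `icr_rigid_transform`.
#' @export
rt_screw <- function(axis, angle, slide = 0) {
  compose_transforms(rt_rotation(axis, angle),
                     rt_translation(slide * axis$direction))
}

is_rigid_transform <- function(x) inherits(x, "icr_rigid_transform")

.check_transform <- function(x, what = "transform") {
  if (!is_rigid_transform(x)) {
    abort(sprintf("`%s` must be an `icr_rigid_transform`.", what),
          class = "icrlab_error_parameter")
  }
  x
}

#' Compose two rigid transforms (apply `first`, then `second`)
#'
#' @param first,second `icr_rigid_transform` objects.
#' @return The composite transform.
#' @export
compose_transforms <- function(first, second) {
  .check_transform(first, "first"); .check_transform(second, "second")
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) + second$translation)
}

#' Invert a rigid transform
#' @param transform An `icr_rigid_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  .check_transform(transform)
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Apply a rigid transform to a body
#' @param body An `icr_body`.
#' @param transform An `icr_rigid_transform`.
#' @return The transformed `icr_body`.
#' @export
apply_transform <- function(body, transform) {
  .check_body(body); .check_transform(transform)
  m <- body_matrix(body) %*% t(transform$rotation)
  .rebuild_body(body, sweep(m, 2L, transform$translation, `+`))
}

#' @export
print.icr_rigid_transform <- function(x, ...) {
  cat("<rigid transform>\nrotation:\n")
  print(round(x$rotation, 9))
  cat(sprintf("translation: (%.6g, %.6g, %.6g) mm\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}
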