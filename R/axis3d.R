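#' Oriented line (rotation axis) in 3D
#'
#' An axis is an infinite line given by an anchor point (mm) and a unit
#' direction. Because a rotation axis is an unoriented line, the direction is
#' stored in canonical form by default: flipped so that its first nonzero
#' component among (x, y, z) is positive. All line metrics
#' ([axis_distance()], [axis_angular_deviation()]) are invariant to the
#' anchor chosen along the line and to the sign of the direction.
#'
#' @param anchor Numeric length-3, a point on the line (mm).
#' @param direction Numeric length-3; normalized internally.
#' @param canonical Flip `direction` to canonical sign? Set `FALSE` when the
#'   orientation carries meaning (e.g. the positive rotation sense returned
#'   by [screw_axis()]).
#' @return An object of class `icr_axis3d`.
#' @examples
#' hinge <- axis3d(c(0, 0, 40), c(1, 0, 0))
#' axis_distance(hinge, axis3d(c(0, 5, 40), c(-1, 0, 0)))
#' @export
axis3d <- function(anchor, direction, canonical = TRUE) {
  anchor <- .vec3(anchor, "anchor")
  direction <- .unit3(direction, "direction")
  if (canonical) direction <- .canonical_direction(direction)
  structure(list(anchor = anchor, direction = direction),
            class = "icr_axis3d")
}

#' @export
print.icr_axis3d <- function(x, ...) {
  cat(sprintf("<axis3d> anchor (%.6g, %.6g, %.6g) mm, direction (%.6g, %.6g, %.6g)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

is_axis3d <- function(x) inherits(x, "icr_axis3d")

.check_axis <- function(x, what = "axis") {
  if (!is_axis3d(x)) {
    abort(sprintf("`%s` must be an `axis3d` object.", what),
          class = "icrlab_error_parameter")
  }
  x
}

#' Minimum distance between two axes (lines) in mm
#'
#' Perpendicular gap for parallel lines, length of the common perpendicular
#' for skew lines, 0 for intersecting or identical lines. Symmetric and
#' invariant to anchor choice and direction sign.
#'
#' @param a,b `axis3d` objects.
#' @return Distance in mm (scalar, >= 0).
#' @export
axis_distance <- function(a, b) {
  .check_axis(a, "a"); .check_axis(b, "b")
  w <- b$anchor - a$anchor
  n <- .cross3(a$direction, b$direction)
  nn <- .norm3(n)
  if (nn < 1e-10) {
    # parallel: component of the anchor gap perpendicular to the direction
    perp <- w - sum(w * a$direction) * a$direction
    return(.norm3(perp))
  }
  abs(sum(w * n)) / nn
}

#' Angle between two axes in degrees
#'
#' Angle between the canonical directions, folded into \[0, 90\] degrees
#' (the sign of a line direction is not meaningful).
#'
#' @param a,b `axis3d` objects.
#' @return Angle in degrees in \[0, 90\].
#' @export
axis_angular_deviation <- function(a, b) {
  .check_axis(a, "a"); .check_axis(b, "b")
  d <- abs(sum(a$direction * b$direction))
  .rad2deg(acos(min(1, d)))
}

#' Foot of the perpendicular from a point onto an axis
#'
#' @param axis An `axis3d`.
#' @param point Numeric length-3 (mm).
#' @return The closest point of the axis to `point` (mm).
#' @export
axis_foot_point <- function(axis, point) {
  .check_axis(axis)
  point <- .vec3(point, "point")
  w <- point - axis$anchor
  axis$anchor + sum(w * axis$direction) * axis$direction
}

#' Reporting coordinates for a registered axis
#'
#' The conventional place to report an axis relative to a body: the foot of
#' the perpendicular from the body's gravity point (vertex centroid) onto
#' the axis, advanced `offset` mm along the canonical direction. Advancing
#' along the canonical direction makes the report reproducible; the
#' direction sign of a line is otherwise arbitrary.
#'
#' @param axis An `axis3d`.
#' @param body An `icr_body` (see [body()]).
#' @param offset Distance advanced along the axis from the foot point, mm.
#' @return Named numeric length-3 (x, y, z) in mm.
#' @export
report_point <- function(axis, body, offset = 100) {
  .check_axis(axis)
  g <- body_centroid(body)
  u <- .canonical_direction(axis$direction)
  foot <- axis_foot_point(axis, g)
  out <- foot + offset * u
  names(out) <- c("x", "y", "z")
  out
}
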