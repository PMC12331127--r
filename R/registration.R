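#' Least-squares rigid fit between two index-corresponded bodies
#'
#' Closed-form orthogonal-Procrustes (Kabsch) solution: the proper rigid
#' transform minimizing the sum of squared vertex residuals between
#' `source` mapped forward and `target`. When the unconstrained optimum is
#' a reflection (possible for noisy or planar data) the nearest proper
#' rotation is returned instead.
#'
#' @param source,target `icr_body` objects with equal vertex counts and
#'   index correspondence.
#' @return An `icr_rigid_transform` with attribute `rms_residual` (mm).
#' @examples
#' b <- generate_control("random_cloud", n = 50, seed = 1)
#' tf <- rt_rotation(axis3d(c(0, 0, 0), c(0, 0, 1)), 12)
#' fit_rigid(b, apply_transform(b, tf))
#' @export
fit_rigid <- function(source, target) {
  .check_body(source, "source"); .check_body(target, "target")
  if (nrow(source) != nrow(target)) {
    abort("`source` and `target` have different vertex counts.",
          class = "icrlab_error_correspondence")
  }
  S <- body_matrix(source)
  Tm <- body_matrix(target)
  cs <- colMeans(S)
  ct <- colMeans(Tm)
  S0 <- sweep(S, 2L, cs)
  T0 <- sweep(Tm, 2L, ct)
  sv <- svd(S0, nu = 0L, nv = 0L)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1)) {
    abort("Source vertices are collinear: rigid attitude is not identifiable.",
          class = "icrlab_error_degenerate")
  }
  H <- crossprod(S0, T0)           # 3x3 covariance
  dec <- svd(H)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- ct - as.numeric(R %*% cs)
  out <- rigid_transform(R, tr)
  res <- T0 - S0 %*% t(R)
  attr(out, "rms_residual") <- sqrt(mean(rowSums(res * res)))
  out
}

#' Finite helical (screw) axis of a rigid transform
#'
#' Decomposes a proper rigid motion into the unique rotation by `angle`
#' about an axis plus a `slide` along that axis. The returned direction is
#' oriented so that `angle` is positive (right-hand rule) and lies in
#' (0, 180\]: a rotation beyond 180 degrees is the same motion taken in the
#' opposite sense. With zero slide the axis is the 3D instantaneous axis of
#' rotation (ICR). A near-identity rotation has no finite axis (the ICR
#' recedes to infinity: this is the small-angle sensitivity of ICR
#' registration), so an error of class `icrlab_error_pure_translation` is
#' raised below `angle_tol` degrees.
#'
#' @param transform An `icr_rigid_transform`.
#' @param angle_tol Rotation angles below this (degrees) are treated as
#'   pure translation.
#' @return List of class `icr_screw` with elements `axis` (an `axis3d`,
#'   non-canonical orientation matching the positive angle), `angle`
#'   (degrees in (0, 180\]) and `slide` (mm, signed along the direction).
#' @export
screw_axis <- function(transform, angle_tol = 1e-9) {
  .check_transform(transform)
  R <- transform$rotation
  tv <- transform$translation
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  angle <- .rad2deg(acos(ct))
  if (angle < angle_tol) {
    abort(paste0("Rotation angle is (numerically) zero: the motion is a pure ",
                 "translation and the ICR axis is undefined (it recedes to infinity)."),
          class = "icrlab_error_pure_translation")
  }
  if (angle < 179.9) {
    u <- c(R[3L, 2L] - R[2L, 3L],
           R[1L, 3L] - R[3L, 1L],
           R[2L, 1L] - R[1L, 2L]) / (2 * sin(.deg2rad(angle)))
    u <- u / .norm3(u)
  } else {
    # near half-turn: skew part degenerates; use the dominant column of R + I
    B <- R + diag(3)
    j <- which.max(diag(B))
    u <- B[, j] / .norm3(B[, j])
    # fix the sign so the skew part (however small) agrees
    s <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
    if (sum(s * u) < 0) u <- -u
  }
  slide <- sum(tv * u)
  b <- tv - slide * u                      # in-plane translation component
  # anchor of the axis: solves (I - R) c = b with c perpendicular to u
  anchor <- b / 2 + .cross3(u, b) / (2 * tan(.deg2rad(angle) / 2))
  structure(list(axis = axis3d(anchor, u, canonical = FALSE),
                 angle = angle, slide = slide),
            class = "icr_screw")
}

#' @export
print.icr_screw <- function(x, ...) {
  cat(sprintf("<screw axis> angle %.9g deg, slide %.9g mm\n", x$angle, x$slide))
  print(x$axis)
  invisible(x)
}

#' Register the instantaneous axis of rotation between two poses
#'
#' The 3D analogue of the Reuleaux construction: recover the single axis
#' and angle whose pure rotation carries `original` onto `moved`, via a
#' least-squares rigid fit followed by helical-axis decomposition. All the
#' standard descriptors of such a registration are returned: the recovered
#' angle `alpha2`, the displacement `d_axis` of the registered axis from
#' `reference_axis`, their angular deviation, the error-caused displacement
#' ratio `ecd_ratio = d_axis / translation_magnitude` (when a nonzero
#' translation magnitude is associated with the case), the residual
#' `rms_after` of the substitutional screw motion, and the axis coordinates
#' at the conventional [report_point()].
#'
#' @param original,moved Index-corresponded `icr_body` poses related by a
#'   proper rigid motion with a nonzero rotation component.
#' @param reference_axis The original (true) rotation axis the registered
#'   ICR is compared against.
#' @param translation_magnitude Magnitude in mm of the translational
#'   component applied to the case, if any; used only to form `ecd_ratio`.
#' @return An object of class `icr_registration`; see [tidy.icr_registration()].
#' @examples
#' arch <- generate_arch(arch_spec(vertex_count = 600, seed = 3))
#' ax <- default_hinge_axis(arch)
#' moved <- translate_body(rotate_body(arch, ax, 2), c(0, 1, 0))
#' reg <- register_icr(arch, moved, ax, translation_magnitude = 1)
#' reg$ecd_ratio  # about 28.65
#' @export
register_icr <- function(original, moved, reference_axis,
                         translation_magnitude = NULL) {
  .check_axis(reference_axis, "reference_axis")
  t0 <- proc.time()[["elapsed"]]
  tf <- fit_rigid(original, moved)
  sc <- screw_axis(tf)
  d_axis <- axis_distance(reference_axis, sc$axis)
  rebuilt <- rt_screw(sc$axis, sc$angle, sc$slide)
  rms_after <- rms_between(apply_transform(original, rebuilt), moved)
  ecd <- if (!is.null(translation_magnitude) && translation_magnitude > 0) {
    d_axis / translation_magnitude
  } else {
    NA_real_
  }
  structure(list(
    icr_axis = sc$axis,
    alpha2 = sc$angle,
    slide = sc$slide,
    d_axis = d_axis,
    angular_deviation = axis_angular_deviation(reference_axis, sc$axis),
    ecd_ratio = ecd,
    translation_magnitude = translation_magnitude %||% NA_real_,
    rms_after = rms_after,
    fit_rms = attr(tf, "rms_residual"),
    report_coords = report_point(sc$axis, original),
    exec_time = proc.time()[["elapsed"]] - t0
  ), class = "icr_registration")
}

#' @export
print.icr_registration <- function(x, ...) {
  cat(sprintf(paste0("<ICR registration> alpha2 %.9g deg, d_axis %.9g mm, ",
                     "angular deviation %.3g deg\n"),
              x$alpha2, x$d_axis, x$angular_deviation))
  if (is.finite(x$ecd_ratio)) cat(sprintf("EcD ratio: %.6g\n", x$ecd_ratio))
  cat(sprintf("rms after substitutional rotation: %.3g mm\n", x$rms_after))
  invisible(x)
}

#' Planar Reuleaux construction of the instantaneous center of rotation
#'
#' Classical 2D method: the ICR lies at the intersection of the
#' perpendicular bisectors of the displacement segments of two tracked
#' points. Kept as an independent oracle for the 3D screw-axis route.
#'
#' @param p1_before,p1_after,p2_before,p2_after Numeric length-2 points
#'   (mm): two points of the same rigid body before and after the motion.
#' @param tol Displacements shorter than `tol` mm are treated as degenerate.
#' @return Numeric length-2, the planar ICR.
#' @export
reuleaux_2d <- function(p1_before, p1_after, p2_before, p2_after, tol = 1e-12) {
  pts <- lapply(list(p1_before, p1_after, p2_before, p2_after), function(p) {
    p <- as.numeric(p)
    if (length(p) != 2L || !all(is.finite(p))) {
      abort("Points must be finite numeric vectors of length 2.",
            class = "icrlab_error_parameter")
    }
    p
  })
  d1 <- pts[[2L]] - pts[[1L]]
  d2 <- pts[[4L]] - pts[[3L]]
  if (.norm3(c(d1, 0)) < tol || .norm3(c(d2, 0)) < tol) {
    abort("A point did not move: its perpendicular bisector is undefined.",
          class = "icrlab_error_degenerate")
  }
  m1 <- (pts[[1L]] + pts[[2L]]) / 2
  m2 <- (pts[[3L]] + pts[[4L]]) / 2
  # bisector of segment i: points q with (q - mi) . di = 0
  A <- rbind(d1, d2)
  bvec <- c(sum(d1 * m1), sum(d2 * m2))
  det_a <- A[1L, 1L] * A[2L, 2L] - A[1L, 2L] * A[2L, 1L]
  scale <- sqrt(sum(d1 * d1)) * sqrt(sum(d2 * d2))
  if (abs(det_a) < 1e-12 * scale) {
    abort("Perpendicular bisectors are parallel: the motion is a pure translation, no planar ICR exists.",
          class = "icrlab_error_pure_translation")
  }
  as.numeric(solve(A, bvec))
}
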