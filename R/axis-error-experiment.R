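# Setup 2: deliberately misplaced rotation axes. Three error types are
# applied to an unmodified central axis, all of which keep the modified
# axis parallel to the central one:
#   parallel      - shift along the line connecting the axis' closest point
#                   to the body's gravity point (negative = toward the body)
#   perpendicular - shift orthogonal to both the axis and the parallel path
#                   (positive = toward global +z)
#   circular      - rotation about the gravity-point axis parallel to the
#                   central axis (positive = toward the positive
#                   perpendicular side)

# Local frame of a central axis relative to a body: radial (parallel-path)
# unit vector away from the mesh, and the perpendicular-path unit vector.
.axis_error_frame <- function(central, body) {
  g <- body_centroid(body)
  foot <- axis_foot_point(central, g)
  radial <- foot - g
  r <- .norm3(radial)
  if (r < 1e-9) {
    abort("The central axis passes through the gravity point: the parallel error path is undefined.",
          class = "icrlab_error_degenerate")
  }
  p_hat <- radial / r
  q0 <- .cross3(central$direction, p_hat)
  # orient the perpendicular path toward global +z (ties broken toward +y)
  s <- if (abs(q0[3L]) > 1e-12) sign(q0[3L]) else
    if (abs(q0[2L]) > 1e-12) sign(q0[2L]) else 1
  list(g = g, foot = foot, r = r, p_hat = p_hat, q_hat = s * q0, sense = s)
}

.shift_axis <- function(axis, v) axis3d(axis$anchor + v, axis$direction,
                                        canonical = FALSE)

.rotate_axis_about_parallel <- function(axis, g, beta) {
  # rotate an axis about the line through g parallel to it; direction is
  # unchanged, the anchor swings on a circle around g
  R <- .rotation_matrix(axis$direction, beta)
  axis3d(g + as.numeric(R %*% (axis$anchor - g)), axis$direction,
         canonical = FALSE)
}

#' Build the 20 artificially misplaced axes of one set
#'
#' For a central axis and a body, constructs the standard error set: 6
#' parallel shifts (+/-5, +/-10, +/-15 mm along the gravity-point-to-axis
#' line, negative toward the body), 6 perpendicular shifts by the same
#' amounts, and 8 circular rotations (+/-3, +/-6, +/-9, +/-12 degrees about
#' the gravity-point axis parallel to the central one). Every modified axis
#' stays parallel to the central axis; `axis_error_mm` is the line-to-line
#' distance between the two, which for circular errors is the chord
#' `2 r sin(|beta|/2)` swept by the axis' foot point.
#'
#' @param central An `axis3d`, the unmodified central axis.
#' @param body The initial unmanipulated `icr_body`.
#' @param shifts Signed shift magnitudes in mm for the parallel and
#'   perpendicular types.
#' @param rotations Signed rotation magnitudes in degrees for the circular
#'   type.
#' @return A tibble with columns `error_type`, `magnitude`,
#'   `axis_error_mm` and a list-column `axis` of `axis3d` objects.
#' @export
build_error_set <- function(central, body,
                            shifts = c(-15, -10, -5, 5, 10, 15),
                            rotations = c(-12, -9, -6, -3, 3, 6, 9, 12)) {
  .check_axis(central, "central"); .check_body(body)
  fr <- .axis_error_frame(central, body)
  specs <- list()
  for (m in shifts) {
    specs[[length(specs) + 1L]] <- list(error_type = "parallel", magnitude = m,
                                        axis = .shift_axis(central, m * fr$p_hat))
    specs[[length(specs) + 1L]] <- list(error_type = "perpendicular", magnitude = m,
                                        axis = .shift_axis(central, m * fr$q_hat))
  }
  for (b in rotations) {
    specs[[length(specs) + 1L]] <- list(
      error_type = "circular", magnitude = b,
      axis = .rotate_axis_about_parallel(central, fr$g, fr$sense * b))
  }
  out <- tibble(
    error_type = vapply(specs, `[[`, character(1), "error_type"),
    magnitude = vapply(specs, `[[`, numeric(1), "magnitude"),
    axis = lapply(specs, `[[`, "axis")
  )
  out$axis_error_mm <- vapply(out$axis, axis_distance, numeric(1), b = central)
  out[order(match(out$error_type, c("parallel", "perpendicular", "circular")),
            out$magnitude), , drop = FALSE]
}

#' Layout of the central-axis groups
#'
#' Controls where the unmodified central axes of [build_groups()] sit
#' relative to the original axis: parallel steps move outward along the
#' gravity-point line, perpendicular steps alternate to both sides, and
#' circular steps swing around the gravity point. Step sizes are comparable
#' to the in-set error magnitudes so intergroup and in-group scales match.
#'
#' @param parallel_step,perpendicular_step Step size in mm.
#' @param circular_step Step size in degrees.
#' @param n_parallel,n_perpendicular,n_circular Number of groups per path.
#' @return A list of class `icr_group_layout`.
#' @export
group_layout <- function(parallel_step = 10, perpendicular_step = 10,
                         circular_step = 15, n_parallel = 6,
                         n_perpendicular = 6, n_circular = 8) {
  structure(list(parallel_step = parallel_step,
                 perpendicular_step = perpendicular_step,
                 circular_step = circular_step,
                 n_parallel = n_parallel,
                 n_perpendicular = n_perpendicular,
                 n_circular = n_circular),
            class = "icr_group_layout")
}

.signed_steps <- function(n) {
  # 1, -1, 2, -2, ... : alternate sides of the path
  k <- rep(seq_len(ceiling(n / 2)), each = 2L)[seq_len(n)]
  k * rep_len(c(1, -1), n)
}

#' Build the group lattice of central axes
#'
#' One group per central-axis position: the original axis, `n_parallel`
#' axes stepped outward along the parallel path, `n_perpendicular` stepped
#' along the perpendicular path (alternating sides), and `n_circular`
#' swung along the circular path (alternating senses). A secondary series
#' (perpendicular + circular) is re-rooted at the farthest parallel axis to
#' probe whether distance from the body changes the perpendicular/circular
#' behaviour.
#'
#' @param original An `axis3d`, the original (clinically registered) axis.
#' @param body The `icr_body` the axes articulate.
#' @param layout An [group_layout()].
#' @return A tibble with columns `group_id`, `series`
#'   (`"primary"`/`"secondary"`), `path` (`"origin"`, `"parallel"`,
#'   `"perpendicular"`, `"circular"`), `offset` (mm or degrees along the
#'   path) and list-column `axis`.
#' @export
build_groups <- function(original, body, layout = group_layout()) {
  .check_axis(original, "original"); .check_body(body)
  fr <- .axis_error_frame(original, body)
  rows <- list(tibble(group_id = "origin", series = "primary",
                      path = "origin", offset = 0, axis = list(original)))
  par_axes <- list()
  for (k in seq_len(layout$n_parallel)) {
    off <- k * layout$parallel_step
    ax <- .shift_axis(original, off * fr$p_hat)
    par_axes[[k]] <- ax
    rows[[length(rows) + 1L]] <- tibble(group_id = sprintf("par_%+g", off),
                                        series = "primary", path = "parallel",
                                        offset = off, axis = list(ax))
  }
  add_series <- function(rows, root, series, prefix) {
    frr <- .axis_error_frame(root, body)
    for (s in .signed_steps(layout$n_perpendicular)) {
      off <- s * layout$perpendicular_step
      rows[[length(rows) + 1L]] <- tibble(
        group_id = sprintf("%sperp_%+g", prefix, off), series = series,
        path = "perpendicular", offset = off,
        axis = list(.shift_axis(root, off * frr$q_hat)))
    }
    for (s in .signed_steps(layout$n_circular)) {
      off <- s * layout$circular_step
      rows[[length(rows) + 1L]] <- tibble(
        group_id = sprintf("%scirc_%+g", prefix, off), series = series,
        path = "circular", offset = off,
        axis = list(.rotate_axis_about_parallel(root, frr$g,
                                                frr$sense * off)))
    }
    rows
  }
  rows <- add_series(rows, original, "primary", "")
  farthest <- par_axes[[layout$n_parallel]]
  rows <- add_series(rows, farthest, "secondary", "F_")
  dplyr::bind_rows(rows)
}

# Sufficient statistics of the rms-vs-angle objective. Rotating `body`
# about `wrong_axis` by theta and comparing with `target` gives
#   rms^2(theta) = (K + 2 Ec cos(theta) + 2 Es sin(theta)) / n
# because every vertex moves on a circle of fixed radius about the axis;
# the three scalars are accumulated once in O(n).
.rms_theta_stats <- function(body, wrong_axis, target) {
  V <- body_matrix(body)
  Q <- body_matrix(target)
  a <- wrong_axis$anchor
  u <- wrong_axis$direction
  W <- sweep(V, 2L, a)
  wu <- as.numeric(W %*% u)
  M <- outer(wu, u)                 # axial components
  E <- W - M                        # radial components
  S <- cbind(u[2L] * W[, 3L] - u[3L] * W[, 2L],
             u[3L] * W[, 1L] - u[1L] * W[, 3L],
             u[1L] * W[, 2L] - u[2L] * W[, 1L])   # u x w_i
  Rm <- sweep(M, 2L, a, `+`) - Q
  list(n = nrow(V),
       K = sum(E * E) + sum(Rm * Rm),
       Ec = sum(E * Rm),
       Es = sum(S * Rm))
}

.rms_theta <- function(theta_deg, st) {
  th <- .deg2rad(theta_deg)
  sqrt(pmax(0, (st$K + 2 * st$Ec * cos(th) + 2 * st$Es * sin(th)) / st$n))
}

#' Best-overlap rotation about a (wrong) axis
#'
#' Finds the rotation angle about `wrong_axis` that brings `body` as close
#' as possible (lowest rms) to `target`, which was produced by rotating
#' `body` about the *true* axis by `nominal_alpha`. A coarse scan over
#' `nominal_alpha +/- scan_halfwidth` at `scan_step` degrees brackets the
#' minimum (widening and rescanning, flagged in `note`, if the minimum sits
#' on the bracket edge), Brent refinement narrows it, and a final
#' stationary-point polish exploits the fact that the squared objective is
#' a single sinusoid in the angle.
#'
#' @param body The initial `icr_body`.
#' @param wrong_axis The artificially misplaced `axis3d`.
#' @param target The body rotated about the true axis.
#' @param nominal_alpha The rotation applied to produce `target`, degrees.
#' @param scan_halfwidth,scan_step Coarse-scan bracket, degrees.
#' @return List with `theta_star` (degrees), `rms_star` (mm) and `note`
#'   (`NA` or a flag that the bracket had to be widened).
#' @export
best_fit_rotation <- function(body, wrong_axis, target, nominal_alpha,
                              scan_halfwidth = 2, scan_step = 0.01) {
  .check_body(body, "body"); .check_body(target, "target")
  .check_axis(wrong_axis, "wrong_axis")
  st <- .rms_theta_stats(body, wrong_axis, target)
  note <- NA_character_
  hw <- scan_halfwidth
  repeat {
    thetas <- seq(nominal_alpha - hw, nominal_alpha + hw, by = scan_step)
    vals <- .rms_theta(thetas, st)
    i <- which.min(vals)
    if ((i > 1L && i < length(thetas)) || hw >= 180) break
    hw <- hw * 2
    note <- sprintf("scan bracket widened to +/-%g deg", hw)
  }
  lo <- thetas[max(1L, i - 1L)]
  hi <- thetas[min(length(thetas), i + 1L)]
  opt <- stats::optimize(.rms_theta, c(lo, hi), st = st, tol = 1e-12)
  theta <- opt$minimum
  # exact stationary point of K + 2Ec cos + 2Es sin, taken on the branch
  # nearest the bracketed minimum
  cand <- .rad2deg(atan2(-st$Es, -st$Ec))
  cand <- cand + 360 * round((theta - cand) / 360)
  if (.rms_theta(cand, st) <= opt$objective) theta <- cand
  # report the rms from direct geometry: the accumulated statistics lose
  # ~1e-7 mm to cancellation exactly where the true residual is ~0
  rms <- rms_between(rotate_body(body, wrong_axis, theta), target)
  list(theta_star = theta, rms_star = rms, note = note)
}

#' Run the axis-error (Setup 2) experiment
#'
#' For every group's central axis, every set rotation and every one of the
#' 20 misplaced axes of [build_error_set()], rotates the body about the
#' central axis by the set rotation, finds the best-overlap rotation about
#' the misplaced axis, and reports the axis-error-caused final-error ratio
#' `AEcFE = axis_error_mm / rms_star`: the millimetres of axis registration
#' error that would cause 1 mm of residual rms, so larger values mean a
#' more error-tolerant configuration. Degenerate cases with `rms_star` at
#' numerical zero report `AEcFE` as `NA` rather than infinity. Per-case
#' failures are flagged, not fatal.
#'
#' @param body The initial unmanipulated `icr_body`.
#' @param groups Group tibble from [build_groups()]; defaults to the full
#'   layout around [default_hinge_axis()].
#' @param set_alphas Set rotations in degrees.
#' @param shifts,rotations In-set error magnitudes, passed to
#'   [build_error_set()].
#' @return A tibble of class `icr_axis_error_result`, one row per (group x
#'   set rotation x error axis), with columns `group_id`, `series`, `path`,
#'   `group_offset`, `set_alpha`, `error_type`, `error_magnitude`,
#'   `axis_error_mm`, `theta_star`, `rms_star`, `aecfe`, `ok`, `note`.
#' @examples
#' arch <- generate_arch(arch_spec(vertex_count = 600, seed = 3))
#' grp <- build_groups(default_hinge_axis(arch), arch,
#'                     group_layout(n_parallel = 2, n_perpendicular = 2,
#'                                  n_circular = 2))
#' res <- run_axis_error_experiment(arch, grp, set_alphas = c(-1, 1))
#' summarize_axis_error(res)
#' @export
run_axis_error_experiment <- function(body, groups = NULL,
                                      set_alphas = c(-3, -2, -1, 1, 2, 3),
                                      shifts = c(-15, -10, -5, 5, 10, 15),
                                      rotations = c(-12, -9, -6, -3,
                                                    3, 6, 9, 12)) {
  .check_body(body)
  if (is.null(groups)) {
    groups <- build_groups(default_hinge_axis(body), body)
  }
  rows <- list()
  for (gi in seq_len(nrow(groups))) {
    central <- groups$axis[[gi]]
    err_set <- tryCatch(build_error_set(central, body, shifts, rotations),
                        error = function(e) e)
    if (inherits(err_set, "error")) {
      rows[[length(rows) + 1L]] <- tibble(
        group_id = groups$group_id[gi], series = groups$series[gi],
        path = groups$path[gi], group_offset = groups$offset[gi],
        set_alpha = NA_real_, error_type = NA_character_,
        error_magnitude = NA_real_, axis_error_mm = NA_real_,
        theta_star = NA_real_, rms_star = NA_real_, aecfe = NA_real_,
        ok = FALSE, note = conditionMessage(err_set))
      next
    }
    for (alpha in set_alphas) {
      target <- rotate_body(body, central, alpha)
      for (ei in seq_len(nrow(err_set))) {
        res <- tryCatch(
          best_fit_rotation(body, err_set$axis[[ei]], target, alpha),
          error = function(e) e)
        bad <- inherits(res, "error")
        err_mm <- err_set$axis_error_mm[ei]
        rows[[length(rows) + 1L]] <- tibble(
          group_id = groups$group_id[gi], series = groups$series[gi],
          path = groups$path[gi], group_offset = groups$offset[gi],
          set_alpha = alpha, error_type = err_set$error_type[ei],
          error_magnitude = err_set$magnitude[ei],
          axis_error_mm = err_mm,
          theta_star = if (bad) NA_real_ else res$theta_star,
          rms_star = if (bad) NA_real_ else res$rms_star,
          aecfe = if (bad || res$rms_star <= 1e-12) NA_real_ else
            err_mm / res$rms_star,
          ok = !bad,
          note = if (bad) conditionMessage(res) else res$note)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "body_label") <- body_label(body)
  class(out) <- c("icr_axis_error_result", class(out))
  out
}

#' Summarize axis-error results by group and error type
#'
#' @param results An `icr_axis_error_result` tibble.
#' @return A tibble of class `icr_axis_error_summary` with the mean AEcFE
#'   per (group, error type), plus group metadata.
#' @export
summarize_axis_error <- function(results) {
  stopifnot(inherits(results, "icr_axis_error_result"))
  out <- results |>
    dplyr::filter(.data$ok, is.finite(.data$aecfe)) |>
    dplyr::group_by(.data$group_id, .data$series, .data$path,
                    .data$group_offset, .data$error_type) |>
    dplyr::summarise(mean_aecfe = mean(.data$aecfe),
                     sd_aecfe = sd(.data$aecfe),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("icr_axis_error_summary", class(out))
  out
}
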