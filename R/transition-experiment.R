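# Setup 1: sweep rotation angle x translation magnitude x translation
# direction, build the three poses, register ICRs, and tabulate.

#' Sagittal-plane direction labels
#'
#' The rotation axis of the standard setup is parallel to +x, so the plane
#' perpendicular to it (the y-z plane) plays the role of the sagittal
#' plane. Direction labels are resolved there: `f` (forward) = +y, `b`
#' (back) = -y, `u` (up) = +z, `d` (down) = -z, and the four 45-degree
#' diagonals `db`, `df`, `ub`, `uf`. For a general axis the label vector is
#' projected into the plane perpendicular to the axis and renormalized.
#'
#' @param label One of `"b"`, `"d"`, `"db"`, `"df"`, `"f"`, `"u"`, `"ub"`,
#'   `"uf"`, or a numeric length-3 vector (returned projected/normalized).
#' @param axis Optional `axis3d` the direction must be perpendicular to.
#' @return Unit numeric length-3 vector.
#' @export
te_direction_vector <- function(label, axis = NULL) {
  base <- list(
    b  = c(0, -1, 0), f  = c(0, 1, 0),
    d  = c(0, 0, -1), u  = c(0, 0, 1),
    db = c(0, -1, -1) / sqrt(2), df = c(0, 1, -1) / sqrt(2),
    ub = c(0, -1, 1) / sqrt(2), uf = c(0, 1, 1) / sqrt(2)
  )
  v <- if (is.character(label)) {
    if (!label %in% names(base)) {
      abort(sprintf("Unknown direction label '%s'. Use one of: %s.",
                    label, paste(names(base), collapse = ", ")),
            class = "icrlab_error_parameter")
    }
    base[[label]]
  } else {
    .unit3(label, "direction")
  }
  if (!is.null(axis)) {
    .check_axis(axis)
    v <- v - sum(v * axis$direction) * axis$direction
    n <- .norm3(v)
    if (n < 1e-9) {
      abort("Translation direction is parallel to the rotation axis.",
            class = "icrlab_error_geometry")
    }
    v <- v / n
  }
  v
}

#' Default hinge axis for a body
#'
#' The standard study axis: parallel to +x, offset from the body's gravity
#' point by `offset` mm (default 40 mm in +z, the order of magnitude of a
#' condylar axis above a lower dental arch). The EcD ratio is provably
#' independent of the axis position, so the offset only sets the scene.
#'
#' @param body An `icr_body`.
#' @param offset Numeric length-3 offset of the axis anchor from the
#'   centroid, mm.
#' @param direction Axis direction (default +x).
#' @return An `axis3d`.
#' @export
default_hinge_axis <- function(body, offset = c(0, 0, 40),
                               direction = c(1, 0, 0)) {
  axis3d(body_centroid(body) + .vec3(offset, "offset"), direction)
}

#' Build the three poses of a transition case
#'
#' `a1` is the body itself, `a2` the body rotated by `alpha1` about `axis`,
#' and `a3` additionally shifted by the translation ("transitional error")
#' vector: `te_magnitude` mm along the resolved `te_direction`,
#' perpendicular to the axis.
#'
#' @param body An `icr_body`.
#' @param axis An `axis3d`.
#' @param alpha1 Rotation angle in degrees.
#' @param te_direction Direction label or vector (see
#'   [te_direction_vector()]).
#' @param te_magnitude Translation magnitude in mm (>= 0).
#' @return List with elements `a1`, `a2`, `a3` (bodies) and `te_vector`.
#' @export
build_poses <- function(body, axis, alpha1, te_direction, te_magnitude) {
  .check_body(body); .check_axis(axis)
  if (!is.finite(te_magnitude) || te_magnitude < 0) {
    abort("`te_magnitude` must be finite and >= 0.",
          class = "icrlab_error_parameter")
  }
  dir <- te_direction_vector(te_direction, axis)
  te <- te_magnitude * dir
  a2 <- rotate_body(body, axis, alpha1)
  list(a1 = body, a2 = a2, a3 = translate_body(a2, te), te_vector = te)
}

.fmt_num <- function(x) {
  # trailing-zero-free decimal label, e.g. 2 -> "2", 0.01 -> "0.01"
  sub("0+$", "", sub("\\.$", "", format(x, trim = TRUE, scientific = FALSE)))
}

#' Run the transition (Setup 1) experiment
#'
#' For every combination of rotation angle, translation magnitude and
#' sagittal direction, builds the three poses, registers the ICR carrying
#' `a1` onto `a3`, and returns one row of descriptors per case. The default
#' grids are the standard study conditions: 8 angles x 6 magnitudes x 8
#' directions = 384 cases. Registration failures are flagged in the `ok` /
#' `note` columns rather than aborting the sweep.
#'
#' @param body An `icr_body` (data-frame-first: pipes from
#'   [generate_arch()]).
#' @param axis The true rotation axis; default [default_hinge_axis()].
#' @param alphas Rotation angles in degrees.
#' @param magnitudes Translation magnitudes in mm.
#' @param directions Direction labels (see [te_direction_vector()]).
#' @return A tibble of class `icr_transition_result`, one row per case,
#'   with columns `case` (label `"<alpha>_<direction>_<magnitude>"`),
#'   `alpha1`, `direction`, `te_magnitude`, `alpha2`, `d_axis`,
#'   `ecd_ratio`, `angular_deviation`, `angle_important` (= 90 - alpha1/2),
#'   `rms_after`, `report_x/y/z`, `exec_time`, `ok`, `note`. The axis and
#'   body label used are attached as attributes.
#' @examples
#' arch <- generate_arch(arch_spec(vertex_count = 600, seed = 3))
#' res <- run_transition_experiment(arch, alphas = c(2, 4), magnitudes = 1,
#'                                  directions = c("f", "u"))
#' res[, c("case", "ecd_ratio", "alpha2")]
#' @export
run_transition_experiment <- function(body,
                                      axis = default_hinge_axis(body),
                                      alphas = c(2, 2.5, 3, 3.5, 4, 4.5, 6, 9),
                                      magnitudes = c(0.01, 0.05, 0.5, 1, 2, 3),
                                      directions = c("b", "d", "db", "df",
                                                     "f", "u", "ub", "uf")) {
  .check_body(body); .check_axis(axis)
  grid <- expand.grid(direction = directions, te_magnitude = magnitudes,
                      alpha1 = alphas, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # order rows alpha-major for readable reports
  grid <- grid[order(grid$alpha1, grid$direction, grid$te_magnitude), ,
               drop = FALSE]
  rows <- purrr::pmap(grid, function(direction, te_magnitude, alpha1) {
    case <- paste(.fmt_num(alpha1), direction, .fmt_num(te_magnitude),
                  sep = "_")
    base <- tibble(case = case, alpha1 = alpha1, direction = direction,
                   te_magnitude = te_magnitude,
                   angle_important = 90 - alpha1 / 2)
    tryCatch({
      poses <- build_poses(body, axis, alpha1, direction, te_magnitude)
      reg <- register_icr(poses$a1, poses$a3, axis,
                          translation_magnitude = te_magnitude)
      dplyr::mutate(base,
        alpha2 = reg$alpha2, d_axis = reg$d_axis,
        ecd_ratio = reg$ecd_ratio,
        angular_deviation = reg$angular_deviation,
        rms_after = reg$rms_after,
        report_x = reg$report_coords[["x"]],
        report_y = reg$report_coords[["y"]],
        report_z = reg$report_coords[["z"]],
        exec_time = reg$exec_time, ok = TRUE, note = NA_character_)
    }, error = function(e) {
      dplyr::mutate(base,
        alpha2 = NA_real_, d_axis = NA_real_, ecd_ratio = NA_real_,
        angular_deviation = NA_real_, rms_after = NA_real_,
        report_x = NA_real_, report_y = NA_real_, report_z = NA_real_,
        exec_time = NA_real_, ok = FALSE, note = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "axis") <- axis
  attr(out, "body_label") <- body_label(body)
  class(out) <- c("icr_transition_result", class(out))
  out
}

#' Export registered axes as OBJ line segments
#'
#' Writes each registered axis of a transition result as a two-vertex line
#' segment centred on its report point, for visual inspection in any mesh
#' viewer. Coordinates are written as-is (mm, right-handed); viewers
#' following the "Forward: -Z, Up: Y" import convention should be set
#' accordingly.
#'
#' @param result An `icr_transition_result`.
#' @param path Output `.obj` file.
#' @param half_length Half-length of each drawn segment, mm.
#' @return `path`, invisibly.
#' @export
export_axes_obj <- function(result, path, half_length = 50) {
  stopifnot(inherits(result, "icr_transition_result"))
  ok <- result[result$ok %||% TRUE, , drop = FALSE]
  axis <- attr(result, "axis")
  u <- axis$direction
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# icrlab registered axes (line segments, mm)", con)
  for (i in seq_len(nrow(ok))) {
    p <- c(ok$report_x[i], ok$report_y[i], ok$report_z[i])
    a <- p - half_length * u
    b <- p + half_length * u
    writeLines(sprintf("v %.9g %.9g %.9g", c(a[1], b[1]), c(a[2], b[2]),
                       c(a[3], b[3])), con)
  }
  for (i in seq_len(nrow(ok))) {
    writeLines(sprintf("l %d %d", 2L * i - 1L, 2L * i), con)
  }
  invisible(path)
}
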