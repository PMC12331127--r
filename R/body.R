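#' Rigid body as a tibble of vertices
#'
#' A body is a set of labelled 3D vertices (mm), optionally with triangle
#' faces. It is stored as a tibble with columns `x`, `y`, `z` so it chains
#' with dplyr verbs; faces and the label travel as attributes. Rigid
#' registration needs full geometric rank, so at least 3 non-collinear
#' vertices are required.
#'
#' @param vertices A numeric matrix or data frame with 3 columns (x, y, z in
#'   mm), one row per vertex.
#' @param faces Optional integer matrix with 3 columns of 1-based vertex
#'   indices, one row per triangle.
#' @param label Short text label for reports.
#' @return A tibble of class `icr_body` with columns `x`, `y`, `z`.
#' @examples
#' b <- body(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
#' body_centroid(b)
#' @export
body <- function(vertices, faces = NULL, label = "body") {
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices[, 1:3])
  if (!is.matrix(vertices) || ncol(vertices) != 3L || !is.numeric(vertices)) {
    abort("`vertices` must be a numeric matrix/data frame with 3 columns.",
          class = "icrlab_error_parameter")
  }
  if (!all(is.finite(vertices))) {
    abort("`vertices` must be finite.", class = "icrlab_error_parameter")
  }
  n <- nrow(vertices)
  if (n < 3L) {
    abort("A body needs at least 3 vertices.", class = "icrlab_error_degenerate")
  }
  ctr <- sweep(vertices, 2L, colMeans(vertices))
  sv <- svd(ctr, nu = 0L, nv = 0L)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1)) {
    abort("Vertices are collinear; the body has no rigid 3D attitude.",
          class = "icrlab_error_degenerate")
  }
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L || anyNA(faces) ||
        any(faces < 1L) || any(faces > n)) {
      abort("`faces` must be a 3-column matrix of valid 1-based vertex indices.",
            class = "icrlab_error_parameter")
    }
  }
  out <- tibble(x = vertices[, 1L], y = vertices[, 2L], z = vertices[, 3L])
  attr(out, "faces") <- faces
  attr(out, "label") <- as.character(label)
  class(out) <- c("icr_body", class(out))
  out
}

is_body <- function(x) inherits(x, "icr_body")

.check_body <- function(x, what = "body") {
  if (!is_body(x)) {
    abort(sprintf("`%s` must be an `icr_body` (see `body()`).", what),
          class = "icrlab_error_parameter")
  }
  x
}

# vertex coordinates as an n x 3 matrix
body_matrix <- function(body) {
  cbind(x = body$x, y = body$y, z = body$z)
}

# rebuild a body from new coordinates, keeping faces/label
.rebuild_body <- function(template, m) {
  out <- tibble(x = m[, 1L], y = m[, 2L], z = m[, 3L])
  attr(out, "faces") <- attr(template, "faces")
  attr(out, "label") <- attr(template, "label")
  class(out) <- c("icr_body", class(out))
  out
}

#' Gravity point (vertex centroid) of a body
#'
#' @param body An `icr_body`.
#' @return Named numeric length-3 (mm).
#' @export
body_centroid <- function(body) {
  .check_body(body)
  c(x = mean(body$x), y = mean(body$y), z = mean(body$z))
}

#' Faces and label accessors
#' @param body An `icr_body`.
#' @return `body_faces()`: integer matrix of triangles or `NULL`;
#'   `body_label()`: character scalar.
#' @export
body_faces <- function(body) attr(.check_body(body), "faces")

#' @rdname body_faces
#' @export
body_label <- function(body) attr(.check_body(body), "label")

#' Rotate a body about an axis
#'
#' Right-hand-rule rotation by `angle` degrees about `axis`. Distances from
#' every vertex to the axis line, and all inter-vertex distances, are
#' preserved (rigidity).
#'
#' @param body An `icr_body`.
#' @param axis An `axis3d`.
#' @param angle Rotation angle in degrees (finite).
#' @return A new `icr_body`.
#' @export
rotate_body <- function(body, axis, angle) {
  .check_body(body); .check_axis(axis)
  if (length(angle) != 1L || !is.finite(angle)) {
    abort("`angle` must be a single finite number (degrees).",
          class = "icrlab_error_parameter")
  }
  R <- .rotation_matrix(axis$direction, angle)
  m <- body_matrix(body)
  m2 <- sweep(m, 2L, axis$anchor) %*% t(R)
  m2 <- sweep(m2, 2L, axis$anchor, `+`)
  .rebuild_body(body, m2)
}

#' Translate a body
#'
#' @param body An `icr_body`.
#' @param vector Numeric length-3 shift in mm.
#' @return A new `icr_body` with every vertex shifted by exactly `vector`.
#' @export
translate_body <- function(body, vector) {
  .check_body(body)
  v <- .vec3(vector, "vector")
  .rebuild_body(body, sweep(body_matrix(body), 2L, v, `+`))
}

#' Root-mean-square distance between two index-corresponded bodies
#'
#' `sqrt(mean(|a_i - b_i|^2))` over vertices; vertices correspond by index.
#' Zero if and only if the bodies coincide vertexwise.
#'
#' @param a,b `icr_body` objects with equal vertex counts.
#' @return rms distance in mm.
#' @export
rms_between <- function(a, b) {
  .check_body(a, "a"); .check_body(b, "b")
  if (nrow(a) != nrow(b)) {
    abort("Bodies have different vertex counts; no index correspondence.",
          class = "icrlab_error_correspondence")
  }
  d <- body_matrix(a) - body_matrix(b)
  sqrt(mean(rowSums(d * d)))
}
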