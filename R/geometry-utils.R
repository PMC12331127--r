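# Small internal vector helpers. All geometry is in mm / degrees at the API
# boundary; radians appear only inside these functions.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.vec3 <- function(x, what = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || !all(is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric vector of length 3.", what),
          class = "icrlab_error_parameter")
  }
  unname(x)
}

.norm3 <- function(x) sqrt(sum(x * x))

.unit3 <- function(x, what = "direction") {
  x <- .vec3(x, what)
  n <- .norm3(x)
  if (n < 1e-12) {
    abort(sprintf("`%s` has (near-)zero length and cannot be normalized.", what),
          class = "icrlab_error_parameter")
  }
  x / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Rodrigues rotation matrix about unit vector `u` by `angle` degrees,
# right-hand rule.
.rotation_matrix <- function(u, angle) {
  th <- .deg2rad(angle)
  ct <- cos(th)
  st <- sin(th)
  ux <- matrix(c(0, u[3L], -u[2L],
                 -u[3L], 0, u[1L],
                 u[2L], -u[1L], 0), nrow = 3L)
  diag(3L) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

# Flip a direction so its first nonzero component among (x, y, z) is
# positive: the canonical representative of an unoriented line direction.
.canonical_direction <- function(u, tol = 1e-12) {
  for (i in 1:3) {
    if (abs(u[i]) > tol) {
      if (u[i] < 0) u <- -u
      break
    }
  }
  u
}
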