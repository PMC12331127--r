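# Deterministic synthetic bodies: a dental-arch-like band (a parabolic
# horseshoe of vertices with tooth-like bumps) and simple control bodies.
# EcD registration results are provably independent of the body used, so a
# synthetic arch stands in for clinical intraoral scans; the arch only has
# to look like one dimensionally (extent ~50-70 mm, 10^3-10^4 vertices).

#' Specification of a synthetic dental-arch body
#'
#' @param arch_width Left-right extent of the arch, mm.
#' @param arch_depth Front-back extent, mm.
#' @param band_height Height of the vertex band, mm.
#' @param n_teeth Number of tooth-like bumps along the arch.
#' @param bump_amplitude Height of the bumps, mm.
#' @param vertex_count Total vertices (>= 500).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   body.
#' @param origin Where the centroid is placed, mm.
#' @param jitter Amplitude of the seeded vertex jitter (mm) that breaks the
#'   exact grid symmetry, emulating scan roughness.
#' @param label Body label.
#' @return An object of class `icr_arch_spec`.
#' @export
arch_spec <- function(arch_width = 60, arch_depth = 50, band_height = 10,
                      n_teeth = 14, bump_amplitude = 2, vertex_count = 2000,
                      seed = 7, origin = c(0, 0, 0), jitter = 0.05,
                      label = NULL) {
  dims <- c(arch_width, arch_depth, band_height, bump_amplitude)
  if (any(!is.finite(dims)) || any(dims[1:3] <= 0) || bump_amplitude < 0) {
    abort("Arch dimensions must be positive (bump amplitude >= 0).",
          class = "icrlab_error_parameter")
  }
  if (!is.finite(vertex_count) || vertex_count < 500) {
    abort("`vertex_count` must be at least 500.",
          class = "icrlab_error_parameter")
  }
  structure(list(arch_width = arch_width, arch_depth = arch_depth,
                 band_height = band_height, n_teeth = n_teeth,
                 bump_amplitude = bump_amplitude,
                 vertex_count = as.integer(vertex_count),
                 seed = as.integer(seed), origin = .vec3(origin, "origin"),
                 jitter = jitter,
                 label = label %||% sprintf("arch_w%g_s%d", arch_width,
                                            as.integer(seed))),
            class = "icr_arch_spec")
}

#' Two stock arch specifications
#'
#' Two distinct default bodies mirroring the two-scan control design:
#' results that must be body-independent are asserted on both.
#' @return An [arch_spec()].
#' @export
arch_spec_primary <- function() arch_spec(label = "arch_I")

#' @rdname arch_spec_primary
#' @export
arch_spec_control <- function() {
  arch_spec(arch_width = 66, arch_depth = 54, band_height = 12, n_teeth = 12,
            bump_amplitude = 1.5, vertex_count = 1500, seed = 11,
            label = "arch_II")
}

#' Generate a dental-arch-like synthetic body
#'
#' Vertices form a triangulated grid over a parabolic horseshoe centreline
#' (occlusal plane = x-y, height = z) with `n_teeth` sinusoidal bumps that
#' grow toward the top of the band, plus a small seeded jitter. The
#' centroid is translated to `spec$origin`. Deterministic: the same spec
#' and seed reproduce the body bit for bit, and the generator does not
#' disturb the caller's random-number state.
#'
#' @param spec An [arch_spec()].
#' @return An `icr_body` with triangle faces.
#' @examples
#' arch <- generate_arch(arch_spec(vertex_count = 600, seed = 3))
#' nrow(arch)
#' @export
generate_arch <- function(spec = arch_spec()) {
  if (!inherits(spec, "icr_arch_spec")) {
    abort("`spec` must come from `arch_spec()`.", class = "icrlab_error_parameter")
  }
  nh <- max(4L, as.integer(floor(sqrt(spec$vertex_count / 5))))
  nt <- as.integer(ceiling(spec$vertex_count / nh))
  tpar <- seq(-1, 1, length.out = nt)
  hpar <- seq(0, 1, length.out = nh)
  grid <- expand.grid(i = seq_len(nh), j = seq_len(nt),
                      KEEP.OUT.ATTRS = FALSE)
  tt <- tpar[grid$j]
  hh <- hpar[grid$i]
  x <- spec$arch_width / 2 * tt
  y <- spec$arch_depth * (1 - tt^2) - spec$arch_depth / 2
  bump <- spec$bump_amplitude * sin(pi * spec$n_teeth * (tt + 1) / 2)^2
  z <- spec$band_height * hh + bump * hh^2
  m <- cbind(x, y, z)
  withr::with_seed(spec$seed, {
    m <- m + matrix(runif(length(m), -spec$jitter, spec$jitter), ncol = 3L)
  })
  # the grid realizes at least the requested count (nh * nt >= vertex_count)
  m <- sweep(m, 2L, colMeans(m))
  m <- sweep(m, 2L, spec$origin, `+`)
  # triangulate the (nh x nt) grid; vertex (i, j) has index (j-1)*nh + i
  idx <- function(i, j) (j - 1L) * nh + i
  f1 <- f2 <- matrix(0L, nrow = (nh - 1L) * (nt - 1L), ncol = 3L)
  k <- 0L
  for (j in seq_len(nt - 1L)) {
    for (i in seq_len(nh - 1L)) {
      k <- k + 1L
      f1[k, ] <- c(idx(i, j), idx(i + 1L, j), idx(i, j + 1L))
      f2[k, ] <- c(idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
  }
  body(m, faces = rbind(f1, f2), label = spec$label)
}

#' Generate a simple control body
#'
#' `"cube"` gives the 8 corners of a unit cube (plus seeded interior
#' points when `n > 8`); `"random_cloud"` gives `n` seeded uniform points
#' in the unit cube. Both are centred on the origin and deterministic per
#' seed.
#'
#' @param kind `"cube"` or `"random_cloud"`.
#' @param n Number of vertices (>= 4).
#' @param seed Integer seed.
#' @param scale Edge length in mm.
#' @return An `icr_body`.
#' @export
generate_control <- function(kind = c("cube", "random_cloud"), n = 8,
                             seed = 1, scale = 1) {
  kind <- match.arg(kind)
  if (!is.finite(n) || n < 4) {
    abort("`n` must be at least 4.", class = "icrlab_error_parameter")
  }
  n <- as.integer(n)
  # corners ordered so any leading subset of >= 4 spans 3D
  corners <- rbind(c(-1, -1, -1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1),
                   c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1), c(1, 1, 1)) / 2
  m <- if (kind == "cube") {
    if (n <= 8L) {
      corners[seq_len(n), , drop = FALSE]
    } else {
      extra <- withr::with_seed(seed,
        matrix(runif(3L * (n - 8L), -0.5, 0.5), ncol = 3L))
      rbind(corners, extra)
    }
  } else {
    withr::with_seed(seed, matrix(runif(3L * n, -0.5, 0.5), ncol = 3L))
  }
  body(m * scale, label = sprintf("%s_n%d_s%d", kind, n, as.integer(seed)))
}
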