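test_that("fit_rigid recovers exact rigid motions", {
  arch <- test_arch()
  idt <- fit_rigid(arch, arch)
  expect_lt(max(abs(idt$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(idt$translation)), 1e-10)
  expect_lt(attr(idt, "rms_residual"), 1e-12)

  ax <- axis3d(c(10, 0, 35), c(0, 1, 1), canonical = FALSE)
  moved <- rotate_body(arch, ax, 7)
  tf <- fit_rigid(arch, moved)
  expect_lt(rms_between(apply_transform(arch, tf), moved), 1e-10)
  expect_lt(attr(tf, "rms_residual"), 1e-10)
  truth <- rt_rotation(ax, 7)
  expect_lt(max(abs(tf$rotation - truth$rotation)), 1e-10)
})

test_that("fit_rigid on noisy poses matches brute-force minimization", {
  withr::with_seed(21, {
    b <- test_cloud(n = 1000, scale = 40)
    tf_true <- compose_transforms(rt_rotation(random_axis(), 25),
                                  rt_translation(c(3, -1, 2)))
    sigma <- 0.01
    noisy <- apply_transform(b, tf_true)
    noise <- matrix(rnorm(3 * nrow(noisy), sd = sigma), ncol = 3)
    target <- body(as.matrix(noisy)[, 1:3] + noise)

    tf <- fit_rigid(b, target)
    expect_lt(max(abs(tf$rotation - tf_true$rotation)), 1e-3)
    expect_lt(max(abs(tf$translation - tf_true$translation)), 1e-2)
    # residual rms ~ sigma * sqrt(3) for isotropic per-coordinate noise
    expect_gt(attr(tf, "rms_residual") / (sigma * sqrt(3)), 0.9)
    expect_lt(attr(tf, "rms_residual") / (sigma * sqrt(3)), 1.05)

    # brute-force oracle over axis-angle + translation (6 parameters)
    obj <- function(p) {
      R <- icrlab:::.rotation_matrix(p[1:3] / sqrt(sum(p[1:3]^2)), p[4])
      pred <- as.matrix(b)[, 1:3] %*% t(R)
      pred <- sweep(pred, 2, p[5:7], `+`)
      mean(rowSums((pred - as.matrix(target)[, 1:3])^2))
    }
    sc <- screw_axis(tf)
    start <- c(sc$axis$direction, sc$angle, tf$translation)
    brute <- optim(start * (1 + 1e-4), obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500))
    expect_lte(mean(rowSums((as.matrix(apply_transform(b, tf))[, 1:3] -
                             as.matrix(target)[, 1:3])^2)),
               brute$value * (1 + 1e-8))
  })
})

test_that("fit_rigid stays a proper rotation even when a reflection fits better", {
  # mirrored cloud: optimal orthogonal map is a reflection, the fit must
  # stay a proper rotation (det +1) and absorb the mismatch as residual
  cl <- test_cloud(n = 60, seed = 8)
  mirrored <- body(as.matrix(cl)[, 1:3] %*% diag(c(-1, 1, 1)))
  tf <- fit_rigid(cl, mirrored)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(tf, "rms_residual"), 0.01)
})

test_that("screw_axis round-trips axis, angle and slide", {
  withr::with_seed(33, {
    for (k in 1:25) {
      ax <- random_axis()
      ang <- runif(1, 0.5, 179)
      sld <- runif(1, -5, 5)
      sc <- screw_axis(rt_screw(ax, ang, sld))
      expect_equal(sc$angle, ang, tolerance = 1e-9)
      expect_equal(sc$slide, sld, tolerance = 1e-8)
      expect_lt(axis_distance(sc$axis, ax), 1e-8)
      # the recovered orientation carries the positive-angle sense
      expect_equal(sum(sc$axis$direction * ax$direction), 1,
                   tolerance = 1e-9)
      rebuilt <- rt_screw(sc$axis, sc$angle, sc$slide)
      b <- test_cloud(n = 20, seed = k)
      expect_lt(rms_between(apply_transform(b, rebuilt),
                            apply_transform(b, rt_screw(ax, ang, sld))),
                1e-9)
    }
  })
})

test_that("screw_axis handles half-turns and opposite-sense input angles", {
  ax <- axis3d(c(0, 4, -2), c(0, 0, 1))
  sc <- screw_axis(rt_rotation(ax, 180))
  expect_equal(sc$angle, 180, tolerance = 1e-6)
  expect_lt(axis_distance(sc$axis, ax), 1e-8)
  # a 300-degree rotation is reported as 60 degrees in the opposite sense
  sc2 <- screw_axis(rt_rotation(ax, 300))
  expect_equal(sc2$angle, 60, tolerance = 1e-9)
  expect_equal(sum(sc2$axis$direction * ax$direction), -1, tolerance = 1e-9)
})

test_that("screw_axis refuses pure translations", {
  expect_error(screw_axis(rt_translation(c(1, 2, 3))),
               class = "icrlab_error_pure_translation")
  expect_error(screw_axis(rt_identity()),
               class = "icrlab_error_pure_translation")
})

test_that("rotation + perpendicular translation displaces the axis by |te|/(2 sin(a/2))", {
  arch <- test_arch()
  ax <- default_hinge_axis(arch)
  withr::with_seed(14, {
    for (alpha in c(2, 9, 60, 145)) {
      te_mag <- runif(1, 0.1, 3)
      te <- te_mag * random_perp(ax$direction)
      tf <- compose_transforms(rt_rotation(ax, alpha), rt_translation(te))
      sc <- screw_axis(tf)
      expect_equal(axis_distance(ax, sc$axis),
                   te_mag / (2 * sin(alpha * pi / 360)), tolerance = 1e-9)
      expect_equal(axis_angular_deviation(ax, sc$axis), 0, tolerance = 1e-7)
      expect_equal(sc$slide, 0, tolerance = 1e-9)
    }
  })
})

test_that("register_icr recovers a pure rotation's axis exactly", {
  arch <- test_arch()
  ax <- default_hinge_axis(arch)
  reg <- register_icr(arch, rotate_body(arch, ax, 4.5), ax)
  expect_lt(reg$d_axis, 1e-6)
  expect_equal(reg$alpha2, 4.5, tolerance = 1e-9)
  expect_lt(reg$angular_deviation, 1e-6)
  expect_true(is.na(reg$ecd_ratio))
  td <- tidy(reg)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(glance(reg),
               c("alpha2", "d_axis", "angular_deviation", "rms_after",
                 "fit_rms"))
})

test_that("register_icr reproduces the benchmark EcD ratios", {
  arch <- test_arch()
  ax <- default_hinge_axis(arch)
  for (alpha in c(2, 4, 6)) {
    poses <- build_poses(arch, ax, alpha, "d", 1)
    reg <- register_icr(poses$a1, poses$a3, ax, translation_magnitude = 1)
    expect_equal(round(reg$ecd_ratio, 2),
                 round(1 / (2 * sin(alpha * pi / 360)), 2))
  }
  # 2 deg, 1 mm: the canonical 28.65
  poses <- build_poses(arch, ax, 2, "f", 1)
  reg <- register_icr(poses$a1, poses$a3, ax, translation_magnitude = 1)
  expect_equal(round(reg$ecd_ratio, 2), 28.65)
  # 60 deg, 1 mm: sine of 30 deg makes d_axis exactly 1
  poses <- build_poses(arch, ax, 60, "f", 1)
  reg <- register_icr(poses$a1, poses$a3, ax, translation_magnitude = 1)
  expect_equal(reg$d_axis, 1, tolerance = 1e-9)
})

test_that("EcD is independent of the body used", {
  ax0 <- axis3d(c(0, 0, 40), c(1, 0, 0))
  bodies <- list(generate_arch(arch_spec(vertex_count = 600, seed = 3)),
                 generate_arch(arch_spec(vertex_count = 520, seed = 19,
                                         arch_width = 66)),
                 test_cloud(n = 50, seed = 2, scale = 25))
  ecds <- vapply(bodies, function(b) {
    bb <- translate_body(b, -body_centroid(b))  # common frame
    poses <- build_poses(bb, ax0, 3, "u", 0.5)
    register_icr(poses$a1, poses$a3, ax0, 0.5)$ecd_ratio
  }, numeric(1))
  expect_lt(max(ecds) - min(ecds), 1e-9)
})

test_that("reuleaux_2d agrees with hand geometry and the analytic center", {
  # unit square corners rotated 90 degrees about the origin
  expect_vec_equal(reuleaux_2d(c(1, 0), c(0, 1), c(0, 1), c(-1, 0)),
                   c(0, 0), tol = 1e-12)
  # rotation about (10, 0) by 2 degrees plus translation (0, 1):
  # the planar ICR must match the analytic 3D prediction projected to 2D
  rot2d <- function(p, c0, ang) {
    th <- ang * pi / 180
    c0 + c(cos(th) * (p - c0)[1] - sin(th) * (p - c0)[2],
           sin(th) * (p - c0)[1] + cos(th) * (p - c0)[2])
  }
  move <- function(p) rot2d(p, c(10, 0), 2) + c(0, 1)
  p1 <- c(3, -2); p2 <- c(-4, 5)
  icr2 <- reuleaux_2d(p1, move(p1), p2, move(p2))
  # analytic: axis +x maps the (y, z) sagittal plane to this 2D picture
  o <- axis3d(c(0, 10, 0), c(1, 0, 0))
  pred <- predicted_icr(o, c(0, 0, 1), 2)
  expect_vec_equal(icr2, pred$anchor[2:3], tol = 1e-9)
  # pure translation: equal displacements
  expect_error(reuleaux_2d(c(0, 0), c(1, 1), c(5, 0), c(6, 1)),
               class = "icrlab_error_pure_translation")
  expect_error(reuleaux_2d(c(0, 0), c(0, 0), c(1, 0), c(0, 1)),
               class = "icrlab_error_degenerate")
})

test_that("planar cases: 2D bisectors and 3D screw axis locate the same center", {
  withr::with_seed(9, {
    for (k in 1:8) {
      alpha <- runif(1, 1, 170)
      center_yz <- runif(2, -20, 20)
      te_yz <- runif(2, -2, 2)
      o <- axis3d(c(0, center_yz), c(1, 0, 0))
      tf <- compose_transforms(rt_rotation(o, alpha),
                               rt_translation(c(0, te_yz)))
      sc <- screw_axis(tf)
      # two tracked points in the sagittal plane x = 0
      p1 <- c(5, -7); p2 <- c(-11, 2)
      mv <- function(p) {
        q <- tf$rotation %*% c(0, p) + tf$translation
        q[2:3]
      }
      icr2 <- reuleaux_2d(p1, mv(p1), p2, mv(p2))
      # intersection of the screw axis with the plane x = 0
      tpar <- -sc$axis$anchor[1] / sc$axis$direction[1]
      cross3d <- sc$axis$anchor + tpar * sc$axis$direction
      expect_vec_equal(icr2, cross3d[2:3], tol = 1e-8)
    }
  })
})
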