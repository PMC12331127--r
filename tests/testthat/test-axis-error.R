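test_that("build_error_set makes 20 parallel modified axes with the right errors", {
  arch <- test_arch()
  central <- default_hinge_axis(arch)
  es <- build_error_set(central, arch)
  expect_equal(nrow(es), 20)
  expect_equal(as.integer(table(es$error_type)[c("parallel", "perpendicular",
                                                 "circular")]),
               c(6L, 6L, 8L))
  # every modified axis stays parallel to the central one
  devs <- vapply(es$axis, axis_angular_deviation, numeric(1), b = central)
  expect_lt(max(devs), 1e-9)
  # plain shifts carry their own magnitude as axis error
  lin <- es[es$error_type != "circular", ]
  expect_equal(lin$axis_error_mm, abs(lin$magnitude), tolerance = 1e-12)
  # circular errors: chord of the rotated foot point, 2 r sin(beta/2)
  g <- body_centroid(arch)
  r <- sqrt(sum((axis_foot_point(central, g) - g)^2))
  circ <- es[es$error_type == "circular", ]
  expect_equal(circ$axis_error_mm,
               2 * r * sin(abs(circ$magnitude) * pi / 360),
               tolerance = 1e-9)
  expect_equal(round(2 * r * sin(3 * pi / 360), 3), 2.094)
  # negative parallel error moves the axis toward the mesh
  near <- es$axis[[which(es$error_type == "parallel" & es$magnitude == -5)]]
  far <- es$axis[[which(es$error_type == "parallel" & es$magnitude == 5)]]
  dist_g <- function(a) sqrt(sum((axis_foot_point(a, g) - g)^2))
  expect_equal(dist_g(near), r - 5, tolerance = 1e-9)
  expect_equal(dist_g(far), r + 5, tolerance = 1e-9)
  # the perpendicular path is orthogonal to the axis and the parallel path;
  # here the parallel path is +z, so the tie-break points it toward +y
  up <- es$axis[[which(es$error_type == "perpendicular" & es$magnitude == 5)]]
  disp <- up$anchor - central$anchor
  expect_lt(abs(sum(disp * central$direction)), 1e-12)
  expect_vec_equal(disp, c(0, 5, 0), tol = 1e-9)
  # axis through the gravity point has no parallel path
  expect_error(build_error_set(axis3d(g, c(1, 0, 0)), arch),
               class = "icrlab_error_degenerate")
})

test_that("build_groups lays out the primary and secondary series", {
  arch <- test_arch()
  orig <- default_hinge_axis(arch)
  grp <- build_groups(orig, arch)
  expect_equal(nrow(grp), 21 + 14)
  expect_equal(sum(grp$series == "primary"), 21)
  expect_equal(sum(grp$series == "secondary"), 14)
  expect_equal(as.integer(table(grp$path)[c("origin", "parallel",
                                            "perpendicular", "circular")]),
               c(1L, 6L, 12L, 16L))
  # parallel group k sits k * step from the original axis
  par <- grp[grp$path == "parallel", ]
  d <- vapply(par$axis, axis_distance, numeric(1), b = orig)
  expect_equal(sort(d), seq(10, 60, by = 10), tolerance = 1e-9)
  # circular-path groups stay parallel to the original
  devs <- vapply(grp$axis, axis_angular_deviation, numeric(1), b = orig)
  expect_lt(max(devs), 1e-9)
  # secondary series is rooted at the farthest parallel axis
  far <- par$axis[[which.max(par$offset)]]
  sec_perp <- grp[grp$series == "secondary" & grp$path == "perpendicular", ]
  d2 <- vapply(sec_perp$axis, axis_distance, numeric(1), b = far)
  expect_equal(sort(d2), c(10, 10, 20, 20, 30, 30), tolerance = 1e-9)
})

test_that("best_fit_rotation finds the optimum and matches a brute-force scan", {
  arch <- generate_arch(arch_spec(vertex_count = 520, seed = 5))
  central <- default_hinge_axis(arch)
  target <- rotate_body(arch, central, 2)
  # correct axis: recovers the nominal angle with vanishing rms
  exact <- best_fit_rotation(arch, central, target, 2)
  expect_equal(exact$theta_star, 2, tolerance = 1e-9)
  expect_lt(exact$rms_star, 1e-10)

  # independent brute-force oracle on raw matrices (own Rodrigues formula)
  V <- as.matrix(arch)[, 1:3]
  Q <- as.matrix(target)[, 1:3]
  brute_scan <- function(wrong, res = 1e-4) {
    u <- wrong$direction
    W <- sweep(V, 2, wrong$anchor)
    thetas <- seq(0.5, 3.5, by = res)
    vals <- vapply(thetas, function(th) {
      thr <- th * pi / 180
      K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
      R <- diag(3) + sin(thr) * K + (1 - cos(thr)) * (K %*% K)
      P <- sweep(W %*% t(R), 2, wrong$anchor, `+`)
      sqrt(mean(rowSums((P - Q)^2)))
    }, numeric(1))
    list(theta = thetas[which.min(vals)], rms = min(vals))
  }
  es <- build_error_set(central, arch)
  withr::with_seed(3, picks <- sample(nrow(es), 4))
  for (i in picks) {
    wrong <- es$axis[[i]]
    bf <- best_fit_rotation(arch, wrong, target, 2)
    oracle <- brute_scan(wrong)
    expect_equal(bf$theta_star, oracle$theta, tolerance = 1e-3,
                 ignore_attr = TRUE)
    expect_lte(bf$rms_star, oracle$rms + 1e-9)
    # optimizing never does worse than staying at the nominal angle
    nominal_rms <- rms_between(rotate_body(arch, wrong, 2), target)
    expect_lt(bf$rms_star, nominal_rms)
  }
  # a parallel error away from the mesh enlarges the circle: less angle
  far <- es$axis[[which(es$error_type == "parallel" & es$magnitude == 15)]]
  expect_lt(best_fit_rotation(arch, far, target, 2)$theta_star, 2)
})

test_that("the sinusoid objective agrees with direct rms evaluation", {
  arch <- generate_arch(arch_spec(vertex_count = 520, seed = 5))
  central <- default_hinge_axis(arch)
  target <- rotate_body(arch, central, -2)
  wrong <- axis3d(central$anchor + c(0, 3, 7), central$direction,
                  canonical = FALSE)
  st <- icrlab:::.rms_theta_stats(arch, wrong, target)
  for (th in c(-3.7, -2, -1.9, 0, 2.4)) {
    expect_equal(icrlab:::.rms_theta(th, st),
                 rms_between(rotate_body(arch, wrong, th), target),
                 tolerance = 1e-10)
  }
})

test_that("axis-error experiment reproduces the tolerance ordering", {
  arch <- generate_arch(arch_spec(vertex_count = 520, seed = 5))
  orig <- default_hinge_axis(arch)
  grp <- build_groups(orig, arch, group_layout(n_parallel = 3,
                                               n_perpendicular = 2,
                                               n_circular = 2))
  res <- run_axis_error_experiment(arch, grp, set_alphas = c(-2, 1, 3))
  expect_s3_class(res, "icr_axis_error_result")
  expect_equal(nrow(res), nrow(grp) * 3 * 20)
  expect_true(all(res$ok))
  expect_true(all(res$rms_star >= 0))
  expect_true(all(is.finite(res$aecfe)))

  smry <- summarize_axis_error(res)
  wide <- tidyr::pivot_wider(smry[, c("group_id", "error_type", "mean_aecfe")],
                             names_from = "error_type",
                             values_from = "mean_aecfe")
  # parallel most tolerant, then perpendicular, then circular - everywhere
  expect_true(all(wide$parallel > wide$perpendicular))
  expect_true(all(wide$perpendicular >= wide$circular))
  # parallel tolerance grows with distance from the mesh
  par <- smry[smry$path %in% c("origin", "parallel") &
                smry$series == "primary" & smry$error_type == "parallel", ]
  par <- par[order(par$group_offset), ]
  expect_true(all(diff(par$mean_aecfe) > 0))
  # circular-type means barely move along the circular path
  circ <- smry[smry$path %in% c("origin", "circular") &
                 smry$series == "primary" & smry$error_type == "circular", ]
  expect_lt(diff(range(circ$mean_aecfe)) / mean(circ$mean_aecfe), 1e-3)
})

test_that("perpendicular errors of opposite sign are near-symmetric and scale linearly", {
  arch <- generate_arch(arch_spec(vertex_count = 520, seed = 5))
  orig <- default_hinge_axis(arch)
  grp <- build_groups(orig, arch, group_layout(n_parallel = 1,
                                               n_perpendicular = 1,
                                               n_circular = 1))
  res <- run_axis_error_experiment(arch, grp[grp$path == "origin", ],
                                   set_alphas = c(2))
  perp <- res[res$error_type == "perpendicular", ]
  for (m in c(5, 10, 15)) {
    plus <- perp$aecfe[perp$error_magnitude == m]
    minus <- perp$aecfe[perp$error_magnitude == -m]
    expect_lt(abs(plus - minus) / plus, 0.05)
  }
  # AEcFE nearly constant across magnitudes for the fixed-lever-arm types
  for (ty in c("perpendicular", "circular")) {
    v <- res$aecfe[res$error_type == ty]
    expect_lt((max(v) - min(v)) / mean(v), 0.2)
  }
  # parallel errors change the lever arm itself: tolerance grows strictly
  # with the signed magnitude (toward the mesh = least tolerant)
  par <- res[res$error_type == "parallel", ]
  par <- par[order(par$error_magnitude), ]
  expect_true(all(diff(par$aecfe) > 0))
})
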