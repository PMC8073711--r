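test_that("fit_long_axis recovers exact and noisy cylinder axes", {
  # collinear points: exact line, sign fixed by the distal reference
  pts <- cbind(0, 0:9, 0)
  ax <- fit_long_axis(pts, distal_ref = c(0, -1, 0))
  expect_equal(ax$direction, c(0, 1, 0), tolerance = 1e-12)

  u_true <- c(1, 1, 0) / sqrt(2)
  true_ax <- axis_line(c(1, 2, 3), u_true)
  distal <- c(1, 2, 3) - 10 * u_true
  cyl <- generate_shaft_points(true_ax, radius_mm = 8, length_mm = 50,
                               n_points = 2000, noise_sd = 0, seed = 7)
  for (m in c("pca_centroids", "cylinder_lsq")) {
    fit <- fit_long_axis(cyl, method = m, distal_ref = distal)
    expect_lt(line_angle(fit$direction, u_true), 1e-6)
    expect_gt(sum(fit$direction * u_true), 0)  # proximal orientation
  }

  cyl_n <- generate_shaft_points(true_ax, 8, 50, 2000, noise_sd = 0.3,
                                 seed = 7)
  for (m in c("pca_centroids", "cylinder_lsq")) {
    fit <- fit_long_axis(cyl_n, method = m, distal_ref = distal)
    expect_lt(line_angle(fit$direction, u_true), 0.5 * pi / 180)
  }
})

test_that("fit_long_axis rejects degenerate inputs", {
  expect_error(fit_long_axis(cbind(0, 0:8, 0)), "at least 10")
  set.seed(2)
  sphere <- matrix(rnorm(600), ncol = 3)
  sphere <- 10 * sphere / sqrt(rowSums(sphere^2))
  expect_error(fit_long_axis(sphere), "no dominant axis|spans < 5")
  flat <- cbind(runif(50, 0, 2), runif(50, 0, 2), runif(50, 0, 2))
  expect_error(fit_long_axis(flat), "spans < 5|no dominant axis")
})

test_that("fit_long_axis is rigid-equivariant (noiseless)", {
  u_true <- c(0.2, 1, -0.3)
  true_ax <- axis_line(c(5, -2, 1), u_true / sqrt(sum(u_true^2)))
  cyl <- generate_shaft_points(true_ax, 9, 40, 1500, noise_sd = 0, seed = 3)
  set.seed(11)
  for (i in 1:5) {
    tf <- rigid_transform(rand_rot(), runif(3, -40, 40))
    fit0 <- fit_long_axis(cyl)
    fit1 <- fit_long_axis(apply_transform(tf, cyl))
    expect_lt(line_angle(fit1$direction,
                         drop(tf$rotation %*% fit0$direction)), 1e-9)
    moved_anchor <- drop(apply_transform(tf, fit0$anchor))
    # anchors may differ along the axis; compare perpendicular offset
    delta <- fit1$anchor - moved_anchor
    perp <- delta - sum(delta * fit1$direction) * fit1$direction
    expect_lt(sqrt(sum(perp^2)), 1e-6)
  }
})

test_that("build_frame constructs the documented orthonormal frame", {
  ax <- axis_line(c(0, 0, 0), c(0, 1, 0))
  fr <- build_frame(ax, c(0, 0, 0), c(5, -2, 20), c(0, 0, 0), side = "right")
  expect_equal(fr$ez, c(5, 0, 20) / sqrt(425), tolerance = 1e-12)
  expect_equal(fr$ez[1], 0.2425356, tolerance = 1e-6)
  expect_equal(fr$ey, c(0, 1, 0))
  expect_equal(fr$ex, radius3d:::cross3(fr$ey, fr$ez), tolerance = 1e-12)

  # invariants: orthonormal + right-handed
  B <- cbind(fr$ex, fr$ey, fr$ez)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-9)
  expect_equal(det(B), 1, tolerance = 1e-9)

  expect_error(build_frame(ax, c(0, 0, 0), c(0, 7, 0), c(0, 0, 0)),
               "parallel")
})

test_that("build_frame is equivariant under rotation of the configuration", {
  set.seed(4)
  ax0 <- axis_line(c(0, 0, 0), c(0, 1, 0))
  base0 <- c(-2, 1, -14)
  sty0 <- c(-2, -8, 12)
  for (i in 1:10) {
    R <- rand_rot()
    t <- runif(3, -30, 30)
    tf <- rigid_transform(R, t)
    fr0 <- build_frame(ax0, base0, sty0, c(0, 0, 0))
    ax1 <- axis_line(drop(apply_transform(tf, c(0, 0, 0))),
                     drop(R %*% c(0, 1, 0)))
    fr1 <- build_frame(ax1, drop(apply_transform(tf, base0)),
                       drop(apply_transform(tf, sty0)),
                       drop(apply_transform(tf, c(0, 0, 0))))
    for (axn in c("ex", "ey", "ez"))
      expect_lt(max(abs(fr1[[axn]] - drop(R %*% fr0[[axn]]))), 1e-9)
    expect_lt(max(abs(fr1$origin - drop(apply_transform(tf, fr0$origin)))),
              1e-9)
  }
})

test_that("locate_origin projects the nearest joint-surface point", {
  ax <- axis_line(c(0, 0, 0), c(0, 1, 0))
  set.seed(5)
  plane <- cbind(runif(50, -10, 10), -2, runif(50, -10, 10))
  expect_equal(locate_origin(ax, plane), c(0, -2, 0), tolerance = 1e-12)
  expect_equal(locate_origin(ax, c(0.5, -2.1, 0.3)), c(0, -2.1, 0),
               tolerance = 1e-12)
  expect_error(locate_origin(ax, matrix(numeric(0), 0, 3)), "empty")

  # hemispherical distal cap: apex at (0, -5, 0) for a sphere of radius 10
  # centred at (0, 5, 0); apex axis-parameter recovered within 0.1 mm
  phi <- acos(1 - runif(3000) * (1 - cos(pi / 3)))   # uniform on the cap
  psi <- runif(3000, 0, 2 * pi)
  cap <- cbind(10 * sin(phi) * cos(psi), 5 - 10 * cos(phi),
               10 * sin(phi) * sin(psi))
  expect_lt(abs(locate_origin(ax, cap)[2] - (-5)), 0.1)
})

test_that("to_frame/from_frame invert each other and preserve distance", {
  ax <- axis_line(c(1, 2, 3), c(0.3, 1, -0.2) / sqrt(1.13))
  fr <- build_frame(ax, c(4, 2, -10), c(2, -6, 9), c(1, 2, 3))
  expect_equal(drop(to_frame(fr, fr$origin)), c(x = 0, y = 0, z = 0))

  id <- build_frame(axis_line(c(0, 0, 0), c(0, 1, 0)), c(0, 1, -14),
                    c(0, -8, 12), c(0, 0, 0))
  expect_equal(drop(to_frame(id, c(1, 2, 3))), c(x = 1, y = 2, z = 3),
               tolerance = 1e-12)

  set.seed(6)
  p <- blob_cloud(60)
  q <- to_frame(fr, p)
  expect_lt(max(abs(from_frame(fr, q) - p)), 1e-12)
  expect_lt(max(abs(dist(q) - dist(p))), 1e-9)
})

test_that("frame JSON serialisation round-trips", {
  fr <- build_frame(axis_line(c(1, 2, 3), c(0, 1, 0)), c(1, 3, -11),
                    c(1, -6, 15), c(1.2, 1.9, 3.4), side = "left")
  f <- tempfile(fileext = ".json")
  frame_to_json(fr, f)
  fr2 <- frame_from_json(f)
  expect_equal(fr2$origin, fr$origin, tolerance = 1e-12)
  expect_equal(fr2$ez, fr$ez, tolerance = 1e-12)
  expect_identical(fr2$side, "left")
  unlink(f)
})
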