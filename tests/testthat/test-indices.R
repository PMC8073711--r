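test_that("reference_triad rejects coincident points", {
  expect_error(reference_triad(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)),
               "pairwise distinct")
})

test_that("triad_centroid is the mean and the least-squares point", {
  tri <- reference_triad(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  expect_equal(unname(triad_centroid(tri)), c(1, 1, 0))

  # brute-force grid oracle: centroid minimises sum of squared distances
  set.seed(20)
  tri <- reference_triad(runif(3, -5, 5), runif(3, -5, 5), runif(3, -5, 5))
  ctr <- triad_centroid(tri)
  g <- seq(-5, 5, by = 0.1)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g[abs(g - ctr[3]) < 0.5]))
  ss <- rowSums((grid - matrix(tri[1, ], nrow(grid), 3, TRUE))^2) +
    rowSums((grid - matrix(tri[2, ], nrow(grid), 3, TRUE))^2) +
    rowSums((grid - matrix(tri[3, ], nrow(grid), 3, TRUE))^2)
  best <- grid[which.min(ss), ]
  expect_lt(max(abs(best - ctr)), 0.1 + 1e-9)
})

test_that("triad_area matches Heron's formula and flags collinearity", {
  expect_equal(as.numeric(triad_area(
    reference_triad(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)))), 2.0)

  col <- reference_triad(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  a <- triad_area(col)
  expect_equal(as.numeric(a), 0, tolerance = 1e-12)
  expect_true(attr(a, "degenerate"))

  set.seed(21)
  for (i in 1:50) {
    tri <- reference_triad(rnorm(3, sd = 8), rnorm(3, sd = 8),
                           rnorm(3, sd = 8))
    ab <- sqrt(sum((tri[1, ] - tri[2, ])^2))
    ac <- sqrt(sum((tri[1, ] - tri[3, ])^2))
    bc <- sqrt(sum((tri[2, ] - tri[3, ])^2))
    s <- (ab + ac + bc) / 2
    heron <- sqrt(max(0, s * (s - ab) * (s - ac) * (s - bc)))
    expect_equal(as.numeric(triad_area(tri)), heron, tolerance = 1e-9)
  }
})

test_that("volar_tilt_3d recovers constructed sagittal tilts", {
  flat <- reference_triad(c(0, -5, 15), c(-5, 0, -10), c(5, 0, -10))
  expect_equal(volar_tilt_3d(flat), 0)

  # rotating the sigmoid pair about z by theta gives VT = theta exactly
  for (theta in c(-40, -11, 5, 11, 40)) {
    R <- rot_about(c(0, 0, 1), theta)
    p2 <- drop(R %*% c(-5, 0, -10))
    p3 <- drop(R %*% c(5, 0, -10))
    tri <- reference_triad(c(0, -5, 15), p2, p3)
    expect_equal(volar_tilt_3d(tri), theta, tolerance = 1e-9)
  }
  # vertical limit: volar edge directly distal of dorsal edge
  tri <- reference_triad(c(0, -5, 15), c(0, -3, -10), c(0, 0, -10))
  expect_equal(volar_tilt_3d(tri), 90)
  expect_error(volar_tilt_3d(
    reference_triad(c(0, -5, 15), c(0, 0, -10), c(0, 0, -12))), "coincident")
})

test_that("radial_inclination_3d recovers constructed coronal tilts", {
  flat <- reference_triad(c(0, 0, 15), c(0, 0, -8), c(4, 1, -8))
  expect_equal(radial_inclination_3d(flat), 0)

  for (theta in c(-40, -22, 7, 22, 40)) {
    R <- rot_about(c(1, 0, 0), theta)
    p1 <- drop(R %*% c(0, 0, 15))
    p2 <- drop(R %*% c(0, 0, -8))
    tri <- reference_triad(p1, p2, p2 + c(4, 1, 0))
    expect_equal(radial_inclination_3d(tri), theta, tolerance = 1e-9)
  }
  tri <- reference_triad(c(0, -3, -8), c(0, 0, -8), c(4, 1, -8.5))
  expect_equal(radial_inclination_3d(tri), 90)
})

test_that("direction_label maps signs, side and dead zone", {
  expect_identical(direction_label(c(0, 2, 0)), "proximal")
  expect_identical(direction_label(c(0, 0, 3)), "radial")
  expect_identical(direction_label(c(0, 0, 0)), "none")
  # ordering: z-term, x-term, y-term
  expect_identical(direction_label(c(-1, -1, -1)), "ulnar-palmar-distal")
  expect_identical(direction_label(c(1, 1, 1)), "radial-dorsal-proximal")
  # left wrist mirrors the x meaning only
  expect_identical(direction_label(c(-1, -1, -1), side = "left"),
                   "ulnar-dorsal-distal")
  # dead zone suppresses small components
  expect_identical(direction_label(c(0.2, -3, 0.1), dead_zone = 0.5),
                   "distal")
  expect_identical(direction_label(c(0.2, 0.1, 0), dead_zone = 0.5), "none")
})

test_that("displacement computes per-point vectors, labels and identity", {
  tri <- default_triad()
  d0 <- displacement(tri, tri)
  expect_true(all(d0$magnitudes_mm == 0))
  expect_true(all(d0$labels == "none"))

  shifted <- reference_triad(tri[1, ] + c(0, -3, 0), tri[2, ] + c(0, -3, 0),
                             tri[3, ] + c(0, -3, 0))
  d1 <- displacement(tri, shifted)
  expect_equal(unname(d1$magnitudes_mm), rep(3, 4))
  expect_true(all(d1$labels == "distal"))

  # rotation about the sigmoid-sigmoid line: styloid moves most
  u <- tri[3, ] - tri[2, ]
  R <- rot_about(u, 20)
  rot <- sweep(sweep(unclass(tri), 2, tri[2, ]) %*% t(R), 2, tri[2, ], "+")
  d2 <- displacement(tri, reference_triad(rot[1, ], rot[2, ], rot[3, ]))
  expect_gt(d2$magnitudes_mm["styloid"],
            d2$magnitudes_mm["sigmoid_volar"])
  expect_gt(d2$magnitudes_mm["styloid"],
            d2$magnitudes_mm["sigmoid_dorsal"])
  expect_lt(max(abs(d2$vectors["centroid", ] -
                      colMeans(d2$vectors[1:3, ]))), 1e-12)

  expect_error(displacement(tri, shifted, frame_id_pre = "a",
                            frame_id_post = "b"), "different frames")
})

test_that("indices are invariant under the documented transforms", {
  set.seed(22)
  for (i in 1:10) {
    tri <- default_triad()
    tf <- rigid_transform(rand_rot(), runif(3, -20, 20))
    m <- apply_transform(tf, unclass(tri))
    tri_t <- reference_triad(m[1, ], m[2, ], m[3, ])
    # area is rigid-invariant
    expect_equal(as.numeric(triad_area(tri_t)), as.numeric(triad_area(tri)),
                 tolerance = 1e-9)
    # displacement magnitudes invariant under a joint rigid transform
    pre <- default_triad()
    post_m <- sweep(unclass(pre), 2, c(1, -2, 3), "+")
    post <- reference_triad(post_m[1, ], post_m[2, ], post_m[3, ])
    mp <- apply_transform(tf, unclass(pre))
    mq <- apply_transform(tf, unclass(post))
    d0 <- displacement(pre, post)
    d1 <- displacement(reference_triad(mp[1, ], mp[2, ], mp[3, ]),
                       reference_triad(mq[1, ], mq[2, ], mq[3, ]))
    expect_equal(unname(d1$magnitudes_mm), unname(d0$magnitudes_mm),
                 tolerance = 1e-9)
  }

  # VT/RI invariant under translation and scaling about the centroid
  tri <- default_triad()
  vt0 <- volar_tilt_3d(tri)
  ri0 <- radial_inclination_3d(tri)
  sh <- sweep(unclass(tri), 2, c(5, -7, 2), "+")
  tri_sh <- reference_triad(sh[1, ], sh[2, ], sh[3, ])
  expect_equal(volar_tilt_3d(tri_sh), vt0, tolerance = 1e-9)
  expect_equal(radial_inclination_3d(tri_sh), ri0, tolerance = 1e-9)
  ctr <- triad_centroid(tri)
  sc <- sweep(2.5 * sweep(unclass(tri), 2, ctr), 2, ctr, "+")
  tri_sc <- reference_triad(sc[1, ], sc[2, ], sc[3, ])
  expect_equal(volar_tilt_3d(tri_sc), vt0, tolerance = 1e-9)
  expect_equal(radial_inclination_3d(tri_sc), ri0, tolerance = 1e-9)
})

test_that("2D angles agree with projections and hand-computed values", {
  expect_equal(vt_2d(c(-5, 0), c(5, 0)), 0)
  expect_equal(vt_2d(c(-5, -2), c(5, 0)), atan2(2, 10) * 180 / pi)
  expect_equal(vt_2d(c(-5, -2), c(5, 0)), 11.30993, tolerance = 1e-5)
  expect_error(ri_2d(c(1, 1), c(1, 1)), "coincident")

  # orthographic projection preserves the in-plane angle
  for (theta in c(-30, 11, 25)) {
    R <- rot_about(c(0, 0, 1), theta)
    p2 <- drop(R %*% c(-5, 0, -10))
    p3 <- drop(R %*% c(5, 0, -10))
    tri <- reference_triad(c(0, -5, 15), p2, p3)
    expect_equal(vt_2d(p2[1:2], p3[1:2]), volar_tilt_3d(tri),
                 tolerance = 1e-9)
  }
  tri <- default_triad()
  expect_equal(ri_2d(tri[1, c(3, 2)], tri[2, c(3, 2)]),
               radial_inclination_3d(tri), tolerance = 1e-9)
})
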