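test_that("generate_shaft_points lies on the cylinder and is reproducible", {
  ax <- axis_line(c(1, 2, 3), c(1, 1, 0) / sqrt(2))
  pts <- generate_shaft_points(ax, radius_mm = 8, length_mm = 40,
                               n_points = 400, noise_sd = 0, seed = 50)
  rel <- sweep(pts, 2, ax$anchor)
  along <- drop(rel %*% ax$direction)
  radial <- sqrt(rowSums(rel^2) - along^2)
  expect_lt(max(abs(radial - 8)), 1e-12)

  # noisy cloud: mean radial distance within 3 SE of the radius
  ptsn <- generate_shaft_points(ax, 8, 40, 2000, noise_sd = 0.3, seed = 51)
  reln <- sweep(ptsn, 2, ax$anchor)
  alongn <- drop(reln %*% ax$direction)
  radialn <- sqrt(rowSums(reln^2) - alongn^2)
  expect_lt(abs(mean(radialn) - 8), 3 * 0.3 / sqrt(length(radialn)) + 0.01)

  expect_identical(generate_shaft_points(ax, 8, 40, 400, 0.2, seed = 52),
                   generate_shaft_points(ax, 8, 40, 400, 0.2, seed = 52))
  expect_error(generate_shaft_points(ax, -1, 40), "positive")
})

test_that("apply_fracture_displacement produces exact stated truths", {
  post <- default_triad()
  z <- apply_fracture_displacement(post)
  expect_equal(unclass(z$pre), unclass(post))
  expect_true(all(z$truth$displacement == 0))

  # pure 5 mm shortening: displaced fragment sits proximally
  s <- apply_fracture_displacement(post, shortening_mm = 5)
  expect_true(all(abs(s$truth$displacement -
                        matrix(c(0, 5, 0), 4, 3, TRUE)) < 1e-12))
  d <- displacement(s$pre, post)
  expect_true(all(d$labels == "distal"))
  expect_equal(unname(d$magnitudes_mm), rep(5, 4))

  # dorsal tilt about the sigmoid hinge: styloid moves most
  t20 <- apply_fracture_displacement(post, tilt_deg = 20)
  mags <- sqrt(rowSums(t20$truth$displacement[1:3, ]^2))
  expect_gt(mags["styloid"], mags["sigmoid_volar"])
  expect_gt(mags["styloid"], mags["sigmoid_dorsal"])
  # hinge point itself does not move under pure tilt
  expect_lt(mags["sigmoid_dorsal"], 1e-12)

  # positive tilt displaces the centroid dorsally (+x), negative palmarly
  expect_gt(t20$truth$displacement["centroid", 1], 0)
  expect_lt(apply_fracture_displacement(post, tilt_deg = -20,
      hinge = "volar_rim")$truth$displacement["centroid", 1], 0)

  # inclination loss moves the styloid proximally, sigmoid points barely
  inc <- apply_fracture_displacement(post, inclination_deg = 15)
  expect_gt(inc$truth$displacement["styloid", 2], 0)
  imags <- sqrt(rowSums(inc$truth$displacement[1:3, ]^2))
  expect_gt(imags["styloid"], imags["sigmoid_volar"])
  expect_gt(imags["styloid"], imags["sigmoid_dorsal"])

  # centroid identity exact
  expect_identical(t20$truth$displacement["centroid", ],
                   colMeans(t20$truth$displacement[1:3, ]))
})

test_that("generate_cohort is reproducible with stored exact truth", {
  expect_length(generate_cohort(cohort_spec(n_patients = 0))$patients, 0)

  spec <- cohort_spec(n_patients = 5, seed = 60)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(cohort_landmark_table(a), cohort_landmark_table(b))

  for (p in a$patients) {
    expect_identical(p$truth$displacement["centroid", ],
                     colMeans(p$truth$displacement[1:3, ]))
    # observed = true + noise at the configured scale (sd 0.3, 9 coords)
    expect_lt(max(abs(p$triad_post_obs - unclass(p$triad_post_true))), 2)
  }
})

test_that("cohort displacement magnitudes match a Monte-Carlo oracle", {
  spec <- cohort_spec(n_patients = 800, seed = 61, lab_pose = FALSE,
                      n_rater_cases = 0)
  co <- generate_cohort(spec)
  mags <- vapply(co$patients, function(p)
    sqrt(sum(p$truth$displacement["styloid", ]^2)), numeric(1))

  # independent oracle: sample the generative model directly
  set.seed(987)
  n_mc <- 4000
  mc <- vapply(seq_len(n_mc), function(i) {
    m <- spec$postop_triad_means +
      matrix(rnorm(9, 0, rep(spec$postop_triad_sd, 3)), 3, 3)
    post <- reference_triad(m[1, ], m[2, ], m[3, ])
    dorsal <- runif(1) < spec$dorsal_fraction
    tilt <- radius3d:::rtrunc_norm(1, spec$tilt_mean, spec$tilt_sd,
                                   spec$tilt_range[1], spec$tilt_range[2])
    incl <- radius3d:::rtrunc_norm(1, spec$incl_mean, spec$incl_sd,
                                   spec$incl_range[1], spec$incl_range[2])
    short <- radius3d:::rtrunc_norm(1, spec$short_mean, spec$short_sd,
                                    spec$short_range[1], spec$short_range[2])
    shift <- radius3d:::rtrunc_norm(1, spec$shift_mean, spec$shift_sd,
                                    spec$shift_range[1], spec$shift_range[2])
    sag <- radius3d:::rtrunc_norm(1, spec$sag_mean, spec$sag_sd,
                                  spec$sag_range[1], spec$sag_range[2])
    fr <- apply_fracture_displacement(
      post, if (dorsal) tilt else -tilt, short, shift,
      if (dorsal) "dorsal_rim" else "volar_rim", incl,
      rnorm(3, 0, spec$translation_sd) + c(if (dorsal) sag else -sag, 0, 0))
    sqrt(sum(fr$truth$displacement["styloid", ]^2))
  }, numeric(1))
  se <- sqrt(var(mags) / length(mags) + var(mc) / n_mc)
  expect_lt(abs(mean(mags) - mean(mc)), 3 * se)
})

test_that("default cohort reproduces the dorsal/palmar case split", {
  co <- generate_cohort(cohort_spec(n_patients = 52, seed = 62,
                                    n_rater_cases = 0))
  n_dorsal <- sum(vapply(co$patients, function(p) p$params$dorsal,
                         logical(1)))
  # binomial 99% interval around 39/52
  p0 <- 39 / 52
  half <- 2.576 * sqrt(p0 * (1 - p0) * 52)
  expect_gte(n_dorsal, 39 - half)
  expect_lte(n_dorsal, 39 + half)
})

test_that("export_cohort writes the documented plain-text artefacts", {
  dir <- tempfile("cohort")
  co <- generate_cohort(cohort_spec(n_patients = 2, seed = 63,
                                    n_rater_cases = 2),
                        include_shafts = TRUE, n_shaft_points = 120)
  export_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("landmarks.csv", "truth.csv", "xray.csv", "raters.csv",
      "P001_shaft_pre.ply", "P002_shaft_post.ply")))))
  lm <- read_landmarks(file.path(dir, "landmarks.csv"))
  expect_equal(nrow(lm), 2 * 2 * 5)
  ply <- read_ply_points(file.path(dir, "P001_shaft_pre.ply"))
  expect_equal(dim(ply), dim(co$patients[[1]]$shafts$pre))
  expect_lt(max(abs(ply - co$patients[[1]]$shafts$pre)), 1e-6)
  unlink(dir, recursive = TRUE)
})
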