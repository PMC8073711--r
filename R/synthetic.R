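#' Synthetic cylinder point cloud for the intact shaft
#'
#' Generates points on the surface of a cylinder about `axis`: rings of
#' equally spaced points at evenly spaced stations along the axis, each ring
#' given a random phase, plus optional isotropic Gaussian noise. Because each
#' ring is angularly balanced, every noiseless cross-section centroid lies
#' exactly on the true axis, which makes the generator an exact oracle for
#' [fit_long_axis()].
#'
#' @param axis an [axis_line()]; points are placed from the anchor along the
#'   direction.
#' @param radius_mm,length_mm cylinder dimensions (> 0).
#' @param n_points requested number of points; rounded down to a whole number
#'   of rings.
#' @param noise_sd isotropic Gaussian noise sd per coordinate, mm.
#' @param seed optional integer seed for reproducibility.
#' @return n x 3 matrix of lab-coordinate points.
#' @export
generate_shaft_points <- function(axis, radius_mm = 10, length_mm = 50,
                                  n_points = 600, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(axis, "axis_line"))
  if (radius_mm <= 0 || length_mm <= 0)
    stop("radius_mm and length_mm must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_rings <- max(5L, as.integer(round(n_points / 40)))
  per_ring <- max(3L, n_points %/% n_rings)
  u <- axis$direction
  b1 <- unit3(if (abs(u[1L]) < 0.9) cross3(u, c(1, 0, 0)) else
                cross3(u, c(0, 1, 0)))
  b2 <- cross3(u, b1)
  t_stations <- seq(0, length_mm, length.out = n_rings)
  phases <- stats::runif(n_rings, 0, 2 * pi)
  ang <- rep(2 * pi * (seq_len(per_ring) - 1L) / per_ring, times = n_rings) +
    rep(phases, each = per_ring)
  t_all <- rep(t_stations, each = per_ring)
  pts <- outer(t_all, u) + radius_mm * (outer(cos(ang), b1) +
                                          outer(sin(ang), b2))
  pts <- sweep(pts, 2L, axis$anchor, "+")
  if (noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd), nrow(pts), 3L)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# rejection sampler for a truncated normal (simple; ranges are wide)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(upper, max(lower, mean)), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Impose a fracture displacement on an anatomic (post-operative) triad
#'
#' Inverts the surgical reduction: starting from the reduced (post-operative)
#' triad, produces the displaced (pre-operative) triad by
#' 1. a sagittal tilt: rotation by `tilt_deg` about an axis parallel to the
#'    radial-ulnar (z) axis through the named sigmoid rim point (positive =
#'    dorsal displacement of the distal fragment, negative = palmar);
#' 2. a coronal inclination loss: rotation by `inclination_deg` about the
#'    line through the two sigmoid-notch edge points, signed so that positive
#'    angles move the radial styloid proximally (loss of radial inclination);
#' 3. translations: `shortening_mm` proximally (+y), `shift_mm` radially
#'    (+z), plus any extra `translation` vector.
#'
#' @param post_triad the anatomic [reference_triad()] (frame coordinates).
#' @param tilt_deg sagittal tilt angle, degrees (dorsal positive).
#' @param shortening_mm proximal translation, mm (>= 0 for true shortening).
#' @param shift_mm radial translation, mm (radial positive).
#' @param hinge `"dorsal_rim"` or `"volar_rim"`: sigmoid rim point the
#'   sagittal tilt hinges on.
#' @param inclination_deg coronal inclination change, degrees (default 0).
#' @param translation extra translation noise vector, mm (default zero).
#' @return list with `pre` (the displaced [reference_triad()]) and `truth`,
#'   a list of two 4 x 3 matrices (rows styloid/sigmoid_volar/sigmoid_dorsal/
#'   centroid): `displacement` = pre - post and `reduction` = post - pre.
#' @export
apply_fracture_displacement <- function(post_triad, tilt_deg = 0,
                                        shortening_mm = 0, shift_mm = 0,
                                        hinge = c("dorsal_rim", "volar_rim"),
                                        inclination_deg = 0,
                                        translation = c(0, 0, 0)) {
  hinge <- match.arg(hinge)
  post <- as_triad(post_triad)
  pre <- unclass(post)

  if (tilt_deg != 0) {
    anchor <- post[if (hinge == "dorsal_rim") "sigmoid_dorsal" else
                     "sigmoid_volar", ]
    R <- rotation_about(c(0, 0, 1), tilt_deg)
    pre <- sweep(sweep(pre, 2L, anchor) %*% t(R), 2L, anchor, "+")
  }
  if (inclination_deg != 0) {
    anchor <- post["sigmoid_volar", ]
    u <- unit3(post["sigmoid_dorsal", ] - post["sigmoid_volar", ])
    # negative sense about +u moves an anatomically placed styloid proximally
    R <- rotation_about(u, -inclination_deg)
    pre <- sweep(sweep(pre, 2L, anchor) %*% t(R), 2L, anchor, "+")
  }
  shift_vec <- c(0, shortening_mm, shift_mm) + vec3(translation, "translation")
  pre <- sweep(pre, 2L, shift_vec, "+")

  disp <- pre - unclass(post)
  disp <- rbind(disp, centroid = colMeans(disp))
  pre_triad <- reference_triad(pre[1L, ], pre[2L, ], pre[3L, ])
  list(pre = pre_triad,
       truth = list(displacement = disp, reduction = -disp))
}

#' Specification of a synthetic pre/post cohort
#'
#' Distributions governing a simulated cohort of distal radius fracture
#' patients. Defaults emulate the reported post-operative landmark geometry
#' (position magnitudes about 14.5, 17.3 and 14.2 mm from the origin for the
#' styloid and the sigmoid volar/dorsal edges) and a displacement model of
#' sagittal hinge tilt (dorsal in a fraction 39/52 of cases), coronal
#' inclination loss, proximal shortening and radial shift, with truncated
#' Gaussian parameter distributions and isotropic landmark observation noise.
#'
#' @param n_patients number of patients (>= 0).
#' @param postop_triad_means 3 x 3 matrix of mean post-operative positions
#'   (rows styloid, sigmoid_volar, sigmoid_dorsal; frame coordinates, mm).
#' @param postop_triad_sd per-point per-axis sd of the post-operative
#'   positions (length 3, mm).
#' @param tilt_mean,tilt_sd,tilt_range sagittal tilt magnitude distribution
#'   (degrees; magnitude is truncated to `tilt_range`, then signed dorsal or
#'   palmar).
#' @param incl_mean,incl_sd,incl_range coronal inclination-loss distribution
#'   (degrees).
#' @param short_mean,short_sd,short_range proximal shortening distribution (mm).
#' @param shift_mean,shift_sd,shift_range radial shift distribution (mm).
#' @param sag_mean,sag_sd,sag_range sagittal (dorsal/palmar) shift magnitude
#'   distribution (mm); applied dorsally in dorsal cases, palmarly otherwise.
#' @param translation_sd extra isotropic translation noise sd (mm).
#' @param dorsal_fraction probability a case is displaced dorsally.
#' @param landmark_sd landmark observation noise sd per coordinate (mm).
#' @param xray_sd 2D radiograph landmark noise sd per coordinate (mm).
#' @param rater_sd landmark re-picking noise per coordinate for the two-rater
#'   reliability table (mm).
#' @param n_rater_cases number of (initial) cases measured by both raters.
#' @param lab_pose if `TRUE`, each patient's data are expressed in a random
#'   lab pose (rotation + translation); if `FALSE` everything stays in the
#'   anatomical frame (identity pose).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 52,
                        postop_triad_means = rbind(
                          styloid = c(-2, -8, 11.93),
                          sigmoid_volar = c(-7, 3, -15.5),
                          sigmoid_dorsal = c(6, 3, -12.5)),
                        postop_triad_sd = c(1.04, 1.50, 1.21),
                        tilt_mean = 20, tilt_sd = 10, tilt_range = c(0, 40),
                        incl_mean = 12, incl_sd = 6, incl_range = c(0, 30),
                        short_mean = 6, short_sd = 3, short_range = c(0, 15),
                        shift_mean = 3, shift_sd = 2, shift_range = c(-5, 8),
                        sag_mean = 4, sag_sd = 2, sag_range = c(0, 10),
                        translation_sd = 2,
                        dorsal_fraction = 39 / 52,
                        landmark_sd = 0.3,
                        xray_sd = 1.0,
                        rater_sd = 0.5,
                        n_rater_cases = 20,
                        lab_pose = TRUE,
                        seed = 1L) {
  stopifnot(n_patients >= 0,
            dorsal_fraction >= 0, dorsal_fraction <= 1,
            all(postop_triad_sd >= 0), landmark_sd >= 0, xray_sd >= 0,
            rater_sd >= 0, translation_sd >= 0)
  m <- as_points(postop_triad_means, "postop_triad_means")
  rownames(m) <- c("styloid", "sigmoid_volar", "sigmoid_dorsal")
  structure(list(n_patients = as.integer(n_patients),
                 postop_triad_means = m,
                 postop_triad_sd = rep_len(postop_triad_sd, 3L),
                 tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                 tilt_range = tilt_range,
                 incl_mean = incl_mean, incl_sd = incl_sd,
                 incl_range = incl_range,
                 short_mean = short_mean, short_sd = short_sd,
                 short_range = short_range,
                 shift_mean = shift_mean, shift_sd = shift_sd,
                 shift_range = shift_range,
                 sag_mean = sag_mean, sag_sd = sag_sd, sag_range = sag_range,
                 translation_sd = translation_sd,
                 dorsal_fraction = dorsal_fraction,
                 landmark_sd = landmark_sd, xray_sd = xray_sd,
                 rater_sd = rater_sd,
                 n_rater_cases = as.integer(n_rater_cases),
                 lab_pose = isTRUE(lab_pose),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# canonical sigmoid-base offset from the true styloid (frame coordinates):
# ulnar and slightly proximal, chosen so styloid - base projects to pure +z
sigmoid_base_from_styloid <- function(styloid) styloid + c(0, 9, -26)

#' Generate a synthetic patient cohort with exact ground truth
#'
#' Draws, for each patient, a true post-operative (anatomic) triad, fracture
#' displacement parameters and hence a true pre-operative triad via
#' [apply_fracture_displacement()]; observed landmarks add iid Gaussian
#' noise. All landmarks (including a sigmoid-base and an origin marker) are
#' expressed in a per-patient random lab pose when `spec$lab_pose` is `TRUE`,
#' with optional matching shaft point clouds for axis fitting and
#' registration; simulated radiograph projections and a two-rater
#' reliability table are included.
#'
#' @param spec a [cohort_spec()].
#' @param include_shafts generate shaft point clouds per patient (slower).
#' @param n_shaft_points points per shaft cloud.
#' @param shaft_noise_sd shaft surface noise sd, mm.
#' @return object of class `synthetic_cohort`: list with `spec`, `patients`
#'   (each carrying true frame/pose, true and observed triads, truth
#'   vectors, parameters, x-ray landmarks, optional shafts) and `raters`
#'   (data.frame of two-rater 3D-VT / 3D-RI measurements).
#' @export
generate_cohort <- function(spec = cohort_spec(), include_shafts = FALSE,
                            n_shaft_points = 600, shaft_noise_sd = 0.3) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  patients <- vector("list", spec$n_patients)
  rater_rows <- list()

  for (i in seq_len(spec$n_patients)) {
    post_true <- spec$postop_triad_means +
      matrix(stats::rnorm(9L, 0, rep(spec$postop_triad_sd, 3L)), 3L, 3L)
    post_true <- reference_triad(post_true[1L, ], post_true[2L, ],
                                 post_true[3L, ])

    dorsal <- stats::runif(1L) < spec$dorsal_fraction
    tilt <- rtrunc_norm(1L, spec$tilt_mean, spec$tilt_sd,
                        spec$tilt_range[1L], spec$tilt_range[2L])
    incl <- rtrunc_norm(1L, spec$incl_mean, spec$incl_sd,
                        spec$incl_range[1L], spec$incl_range[2L])
    short <- rtrunc_norm(1L, spec$short_mean, spec$short_sd,
                         spec$short_range[1L], spec$short_range[2L])
    shift <- rtrunc_norm(1L, spec$shift_mean, spec$shift_sd,
                         spec$shift_range[1L], spec$shift_range[2L])
    sag <- rtrunc_norm(1L, spec$sag_mean, spec$sag_sd,
                       spec$sag_range[1L], spec$sag_range[2L])
    sag <- if (dorsal) sag else -sag
    trans <- stats::rnorm(3L, 0, spec$translation_sd)
    params <- list(dorsal = dorsal,
                   tilt_deg = if (dorsal) tilt else -tilt,
                   inclination_deg = incl, shortening_mm = short,
                   shift_mm = shift, sag_shift_mm = sag, translation = trans,
                   hinge = if (dorsal) "dorsal_rim" else "volar_rim")

    fr <- apply_fracture_displacement(post_true, params$tilt_deg, short,
                                      shift, params$hinge, incl,
                                      trans + c(sag, 0, 0))
    pre_true <- fr$pre

    noise <- function(m) m + matrix(stats::rnorm(length(m), 0,
                                                 spec$landmark_sd),
                                    nrow(m), ncol(m))
    pre_obs <- noise(unclass(pre_true))
    post_obs <- noise(unclass(post_true))

    base_true <- sigmoid_base_from_styloid(unclass(post_true)["styloid", ])
    origin_true <- c(0, 0, 0)

    pose <- if (spec$lab_pose) {
      rigid_transform(random_rotation(), stats::runif(3L, -100, 100))
    } else rigid_transform()
    lab <- function(p) apply_transform(pose, p)

    frame_true <- structure(
      list(origin = drop(lab(origin_true)),
           ex = drop(pose$rotation %*% c(1, 0, 0)),
           ey = drop(pose$rotation %*% c(0, 1, 0)),
           ez = drop(pose$rotation %*% c(0, 0, 1)),
           side = "right"),
      class = "anatomical_frame")

    landmarks <- rbind(
      data.frame(stage = "pre",
                 label = c("styloid", "sigmoid_volar", "sigmoid_dorsal",
                           "sigmoid_base", "origin"),
                 lab(rbind(pre_obs, base_true, origin_true))),
      data.frame(stage = "post",
                 label = c("styloid", "sigmoid_volar", "sigmoid_dorsal",
                           "sigmoid_base", "origin"),
                 lab(rbind(post_obs, base_true, origin_true))))

    # simulated radiographs: orthographic projections + 2D picking noise
    xray <- lapply(list(pre = unclass(pre_true), post = unclass(post_true)),
                   function(m) {
      e2 <- function(p) p + stats::rnorm(2L, 0, spec$xray_sd)
      list(lateral_volar = e2(m["sigmoid_volar", c("x", "y")]),
           lateral_dorsal = e2(m["sigmoid_dorsal", c("x", "y")]),
           pa_styloid = e2(m["styloid", c("z", "y")]),
           pa_ulnar = e2(m["sigmoid_volar", c("z", "y")]))
    })

    shafts <- NULL
    if (include_shafts) {
      ax_frame <- axis_line(c(0, 10, 0), c(0, 1, 0))
      mk <- function() {
        s <- generate_shaft_points(ax_frame, radius_mm = 10, length_mm = 50,
                                   n_points = n_shaft_points,
                                   noise_sd = shaft_noise_sd)
        lab(s)
      }
      shafts <- list(pre = mk(), post = mk())
    }

    patients[[i]] <- structure(
      list(patient_id = sprintf("P%03d", i), side = "right", pose = pose,
           frame_true = frame_true,
           triad_pre_true = pre_true, triad_post_true = post_true,
           triad_pre_obs = pre_obs, triad_post_obs = post_obs,
           truth = fr$truth, params = params,
           landmarks = landmarks, xray = xray, shafts = shafts),
      class = "synthetic_patient")

    if (i <= spec$n_rater_cases) {
      for (rater in c("A", "B")) {
        picked <- unclass(post_true) +
          matrix(stats::rnorm(9L, 0, spec$rater_sd), 3L, 3L)
        t3 <- reference_triad(picked[1L, ], picked[2L, ], picked[3L, ])
        rater_rows[[length(rater_rows) + 1L]] <- data.frame(
          patient_id = sprintf("P%03d", i), rater = rater,
          vt_deg = volar_tilt_3d(t3), ri_deg = radial_inclination_3d(t3))
      }
    }
  }

  raters <- if (length(rater_rows)) do.call(rbind, rater_rows) else
    data.frame(patient_id = character(), rater = character(),
               vt_deg = numeric(), ri_deg = numeric())
  structure(list(spec = spec, patients = patients, raters = raters),
            class = "synthetic_cohort")
}

#' Export a synthetic cohort to plain-text files
#'
#' Writes the landmark CSV (dialect of [read_landmarks()]), a ground-truth
#' CSV (`patient_id, point, dx, dy, dz` of the true pre - post displacement),
#' the simulated radiograph landmark CSV, the two-rater table, and (when
#' shaft clouds are present) one ASCII PLY point cloud per patient and stage.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lm <- do.call(rbind, lapply(cohort$patients, function(p)
    cbind(patient_id = p$patient_id, p$landmarks, side = p$side)))
  lm_path <- file.path(dir, "landmarks.csv")
  utils::write.csv(lm, lm_path, row.names = FALSE)

  truth <- do.call(rbind, lapply(cohort$patients, function(p) {
    d <- p$truth$displacement
    data.frame(patient_id = p$patient_id, point = rownames(d),
               dx = d[, 1L], dy = d[, 2L], dz = d[, 3L])
  }))
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, truth_path, row.names = FALSE)

  xr <- do.call(rbind, lapply(cohort$patients, function(p)
    do.call(rbind, lapply(names(p$xray), function(st) {
      x <- p$xray[[st]]
      data.frame(patient_id = p$patient_id, stage = st,
                 landmark = names(x),
                 u = vapply(x, `[`, numeric(1L), 1L),
                 v = vapply(x, `[`, numeric(1L), 2L))
    }))))
  xr_path <- file.path(dir, "xray.csv")
  utils::write.csv(xr, xr_path, row.names = FALSE)

  raters_path <- file.path(dir, "raters.csv")
  utils::write.csv(cohort$raters, raters_path, row.names = FALSE)

  paths <- c(lm_path, truth_path, xr_path, raters_path)
  for (p in cohort$patients) {
    if (!is.null(p$shafts)) {
      for (st in c("pre", "post")) {
        f <- file.path(dir, sprintf("%s_shaft_%s.ply", p$patient_id, st))
        write_ply_points(p$shafts[[st]], f)
        paths <- c(paths, f)
      }
    }
  }
  invisible(paths)
}
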