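#' Configuration for an end-to-end cohort run
#'
#' @param landmarks landmark table: path to CSV/JSON in the
#'   [read_landmarks()] dialect, or an equivalent data.frame.
#' @param shafts optional shaft geometry for frame construction and
#'   registration: a directory containing `<patient>_shaft_<stage>.ply` (or
#'   `.stl`) files, or a named list `patient_id -> list(pre =, post =)` of
#'   point matrices. When absent, landmark coordinates are assumed to be
#'   already expressed in (or pre-registered to) the anatomical frame.
#' @param raters optional two-rater reliability table (path or data.frame
#'   with `patient_id, rater, vt_deg, ri_deg`).
#' @param xray optional radiograph landmark table (path or data.frame with
#'   `patient_id, stage, landmark, u, v`; landmarks `lateral_volar`,
#'   `lateral_dorsal`, `pa_styloid`, `pa_ulnar`). When absent, 2D angles are
#'   simulated by orthographic projection of the 3D landmarks.
#' @param axis_method passed to [fit_long_axis()].
#' @param use_icp run ICP registration of the pre shaft onto the post shaft
#'   and apply the transform to the pre-operative landmarks.
#' @param icp_max_iter,icp_tol ICP settings.
#' @param mirror_left mirror left wrists to the right-wrist convention
#'   (negate the frame x coordinate) so cohort statistics pool sides.
#' @param dead_zone dead zone (mm) for direction labels.
#' @param alpha significance level for the statistical workflow, in (0, 1).
#' @param seed integer seed (the pipeline is deterministic; the seed guards
#'   any stochastic extension and is recorded in the report).
#' @param out_dir optional output directory for report files.
#' @return object of class `run_config`.
#' @export
run_config <- function(landmarks, shafts = NULL, raters = NULL, xray = NULL,
                       axis_method = "pca_centroids", use_icp = !is.null(shafts),
                       icp_max_iter = 200, icp_tol = 1e-6,
                       mirror_left = TRUE, dead_zone = 0, alpha = 0.05,
                       seed = 1L, out_dir = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.character(landmarks) && !file.exists(landmarks))
    stop("landmark file does not exist: ", landmarks)
  if (is.character(shafts) && !dir.exists(shafts))
    stop("shaft directory does not exist: ", shafts)
  structure(list(landmarks = landmarks, shafts = shafts, raters = raters,
                 xray = xray, axis_method = axis_method,
                 use_icp = isTRUE(use_icp), icp_max_iter = icp_max_iter,
                 icp_tol = icp_tol, mirror_left = isTRUE(mirror_left),
                 dead_zone = dead_zone, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

read_table_arg <- function(x) {
  if (is.null(x) || is.data.frame(x)) return(x)
  utils::read.csv(x, stringsAsFactors = FALSE)
}

load_patient_shafts <- function(shafts, pid) {
  if (is.null(shafts)) return(NULL)
  if (is.list(shafts)) return(shafts[[pid]])
  out <- list()
  for (st in c("pre", "post")) {
    for (ext in c("ply", "stl")) {
      f <- file.path(shafts, sprintf("%s_shaft_%s.%s", pid, st, ext))
      if (file.exists(f)) {
        out[[st]] <- read_mesh_points(f)
        break
      }
    }
  }
  if (!length(out)) NULL else out
}

mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))

modal_label <- function(labels) {
  t <- table(labels)
  names(t)[which.max(t)]
}

#' Run the full measurement and statistics pipeline on a cohort
#'
#' For every patient: constructs the anatomical frame (long-axis fit on the
#' post-operative shaft, z-axis from the sigmoid-base/styloid landmarks,
#' origin on the axis; optional ICP registration of the pre-operative shaft
#' onto the post-operative one), expresses the reference triads in the frame,
#' and computes the triad indices and displacement record. Cohort-level
#' statistics mirror the study workflow: per-point positions and movement
#' (mean +/- SD, modal anatomical direction), Shapiro-Wilk screening,
#' Friedman plus Scheffe-type post-hoc on per-point movement distances,
#' Wilcoxon signed-rank on pre/post plane areas, Pearson correlation of 2D vs
#' 3D volar tilt and radial inclination, intraclass correlation for the
#' two-rater table when supplied, and dorsal/palmar displacement case counts
#' (sign of the pre-operative centroid x coordinate).
#'
#' @param config a [run_config()].
#' @return object of class `cohort_report`; see [write_report()]. Fields
#'   include `measurements` and `displacements` data.frames, `stats` (the
#'   test results), `counts`, and `log` (per-patient processing notes).
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  lm <- if (is.data.frame(config$landmarks)) config$landmarks else
    read_landmarks(config$landmarks)
  raters <- read_table_arg(config$raters)
  xray <- read_table_arg(config$xray)

  pids <- unique(lm$patient_id)
  meas <- list()
  disp <- list()
  log <- character()
  failed <- character()

  for (pid in pids) {
    res <- tryCatch({
      rows <- lm[lm$patient_id == pid, ]
      side <- rows$side[1L]
      get_pt <- function(stage, label) {
        r <- rows[rows$stage == stage & rows$label == label, ]
        c(r$x, r$y, r$z)
      }
      shafts <- load_patient_shafts(config$shafts, pid)

      if (!is.null(shafts)) {
        ax <- fit_long_axis(shafts$post, method = config$axis_method,
                            distal_ref = get_pt("post", "styloid"))
        frame <- build_frame(ax, get_pt("post", "sigmoid_base"),
                             get_pt("post", "styloid"),
                             locate_origin(ax, get_pt("post", "origin")),
                             side = side)
        pre_pts <- rbind(get_pt("pre", "styloid"),
                         get_pt("pre", "sigmoid_volar"),
                         get_pt("pre", "sigmoid_dorsal"))
        if (config$use_icp && !is.null(shafts$pre)) {
          tf <- register_rigid(shafts$pre, shafts$post,
                               max_iter = config$icp_max_iter,
                               tol = config$icp_tol)
          pre_pts <- apply_transform(tf, pre_pts)
          log <- c(log, sprintf(
            "%s: ICP rms %.4f mm in %d iterations (converged: %s)", pid,
            attr(tf, "rms"), attr(tf, "iterations"), attr(tf, "converged")))
        }
        pre_f <- to_frame(frame, pre_pts)
        post_f <- to_frame(frame, rbind(get_pt("post", "styloid"),
                                        get_pt("post", "sigmoid_volar"),
                                        get_pt("post", "sigmoid_dorsal")))
        log <- c(log, sprintf("%s: axis fit (%s), frame built", pid,
                              config$axis_method))
      } else {
        # no shaft geometry: landmarks are taken as anatomical-frame
        # coordinates (pre-registered input contract)
        pre_f <- rbind(get_pt("pre", "styloid"),
                       get_pt("pre", "sigmoid_volar"),
                       get_pt("pre", "sigmoid_dorsal"))
        post_f <- rbind(get_pt("post", "styloid"),
                        get_pt("post", "sigmoid_volar"),
                        get_pt("post", "sigmoid_dorsal"))
      }

      side_eff <- side
      if (config$mirror_left && side == "left") {
        pre_f[, 1L] <- -pre_f[, 1L]
        post_f[, 1L] <- -post_f[, 1L]
        side_eff <- "right"
        log <- c(log, sprintf("%s: left wrist mirrored to right convention",
                              pid))
      }

      tri_pre <- reference_triad(pre_f[1L, ], pre_f[2L, ], pre_f[3L, ])
      tri_post <- reference_triad(post_f[1L, ], post_f[2L, ], post_f[3L, ])
      idx <- list(pre = triad_indices(tri_pre), post = triad_indices(tri_post))
      d <- displacement(tri_pre, tri_post, side = side_eff,
                        dead_zone = config$dead_zone)

      angles_2d <- function(stage, tri) {
        if (!is.null(xray)) {
          xr <- xray[xray$patient_id == pid & xray$stage == stage, ]
          g <- function(lmk) {
            r <- xr[xr$landmark == lmk, ]
            if (nrow(r) != 1L) stop("missing x-ray landmark ", lmk,
                                    " for patient ", pid, " stage ", stage)
            c(r$u, r$v)
          }
          c(vt = vt_2d(g("lateral_volar"), g("lateral_dorsal")),
            ri = ri_2d(g("pa_styloid"), g("pa_ulnar")))
        } else {
          t3 <- unclass(tri)
          c(vt = vt_2d(t3["sigmoid_volar", c("x", "y")],
                       t3["sigmoid_dorsal", c("x", "y")]),
            ri = ri_2d(t3["styloid", c("z", "y")],
                       t3["sigmoid_volar", c("z", "y")]))
        }
      }

      m_rows <- do.call(rbind, lapply(c("pre", "post"), function(st) {
        tri <- if (st == "pre") tri_pre else tri_post
        t3 <- unclass(tri)
        a2 <- angles_2d(st, tri)
        data.frame(patient_id = pid, stage = st, side = side_eff,
                   styloid_x = t3[1, 1], styloid_y = t3[1, 2],
                   styloid_z = t3[1, 3],
                   sigmoid_volar_x = t3[2, 1], sigmoid_volar_y = t3[2, 2],
                   sigmoid_volar_z = t3[2, 3],
                   sigmoid_dorsal_x = t3[3, 1], sigmoid_dorsal_y = t3[3, 2],
                   sigmoid_dorsal_z = t3[3, 3],
                   centroid_x = idx[[st]]$centroid[1],
                   centroid_y = idx[[st]]$centroid[2],
                   centroid_z = idx[[st]]$centroid[3],
                   area_mm2 = idx[[st]]$area_mm2,
                   vt3d_deg = idx[[st]]$vt_deg, ri3d_deg = idx[[st]]$ri_deg,
                   vt2d_deg = a2[["vt"]], ri2d_deg = a2[["ri"]])
      }))
      d_rows <- data.frame(patient_id = pid, point = rownames(d$vectors),
                           dx = d$vectors[, 1], dy = d$vectors[, 2],
                           dz = d$vectors[, 3],
                           magnitude_mm = d$magnitudes_mm,
                           label = d$labels, row.names = NULL)
      list(meas = m_rows, disp = d_rows)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, pid)
      log <- c(log, sprintf("%s: FAILED: %s", pid, conditionMessage(res)))
    } else {
      meas[[pid]] <- res$meas
      disp[[pid]] <- res$disp
    }
  }

  if (!length(meas))
    stop("no patient could be processed; see log:\n",
         paste(log, collapse = "\n"))
  meas <- do.call(rbind, meas)
  disp <- do.call(rbind, disp)
  rownames(meas) <- rownames(disp) <- NULL
  report <- build_cohort_report(meas, disp, raters, config, failed, log)
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

point_names <- c("styloid", "sigmoid_volar", "sigmoid_dorsal", "centroid")

build_cohort_report <- function(meas, disp, raters, config, failed, log) {
  n <- length(unique(meas$patient_id))
  alpha <- config$alpha

  positions <- list()
  for (st in c("pre", "post")) {
    ms <- meas[meas$stage == st, ]
    for (pt in point_names) {
      cols <- if (pt == "centroid") c("centroid_x", "centroid_y", "centroid_z")
        else paste0(pt, c("_x", "_y", "_z"))
      v <- as.matrix(ms[cols])
      mag <- sqrt(rowSums(v^2))
      labs <- apply(v, 1L, direction_label, side = "right",
                    dead_zone = config$dead_zone)
      positions[[paste(st, pt, sep = ".")]] <- list(
        stage = st, point = pt, n = nrow(ms),
        mean_mm = mean(mag), sd_mm = stats::sd(mag),
        modal_direction = modal_label(labs))
    }
  }

  disp_sum <- lapply(point_names, function(pt) {
    d <- disp[disp$point == pt, ]
    list(point = pt, n = nrow(d), mean_mm = mean(d$magnitude_mm),
         sd_mm = stats::sd(d$magnitude_mm),
         modal_direction = modal_label(d$label))
  })
  names(disp_sum) <- point_names

  mag_mat <- sapply(c("styloid", "sigmoid_volar", "sigmoid_dorsal"),
                    function(pt) disp$magnitude_mm[disp$point == pt])
  normality <- lapply(colnames(mag_mat), function(pt)
    tryCatch(shapiro_wilk(mag_mat[, pt]), error = function(e)
      conditionMessage(e)))
  names(normality) <- colnames(mag_mat)

  fried <- tryCatch(friedman(mag_mat), error = function(e) conditionMessage(e))
  posthoc <- tryCatch(scheffe_posthoc(mag_mat, alpha = alpha),
                      error = function(e) conditionMessage(e))

  area_pre <- meas$area_mm2[meas$stage == "pre"]
  area_post <- meas$area_mm2[meas$stage == "post"]
  area_test <- tryCatch(wilcoxon_signed_rank(area_pre, area_post),
                        error = function(e) {
                          if (grepl("all differences are zero",
                                    conditionMessage(e)))
                            "no change" else conditionMessage(e)
                        })

  cors <- list(
    vt = tryCatch(pearson_r(meas$vt3d_deg, meas$vt2d_deg),
                  error = function(e) conditionMessage(e)),
    ri = tryCatch(pearson_r(meas$ri3d_deg, meas$ri2d_deg),
                  error = function(e) conditionMessage(e)))

  icc <- NULL
  if (!is.null(raters) && nrow(raters)) {
    icc <- lapply(c(vt = "vt_deg", ri = "ri_deg"), function(col) {
      w <- stats::reshape(raters[c("patient_id", "rater", col)],
                          idvar = "patient_id", timevar = "rater",
                          direction = "wide")
      tryCatch(icc_two_way(as.matrix(w[-1L])),
               error = function(e) conditionMessage(e))
    })
  }

  # dorsal/palmar classification from the pre-operative centroid x sign
  pre_cx <- meas$centroid_x[meas$stage == "pre"]
  counts <- list(dorsal = sum(pre_cx > 0), palmar = sum(pre_cx < 0),
                 neutral = sum(pre_cx == 0))

  structure(list(n_patients = n, failed = failed,
                 measurements = meas, displacements = disp,
                 positions = positions, displacement_summary = disp_sum,
                 stats = list(normality = normality, friedman = fried,
                              posthoc = posthoc, area_wilcoxon = area_test,
                              pearson = cors, icc = icc),
                 counts = counts, alpha = alpha, seed = config$seed,
                 log = log),
            class = "cohort_report")
}

fmt_ms <- function(m, s) sprintf("%.1f +/- %.1f", m, s)

#' Write a cohort report to disk
#'
#' Emits `report.json` (full precision), `report.txt` (human-readable, mm and
#' degrees rounded to one decimal), `measurements.csv` and
#' `displacements.csv`, plus `log.txt` with the per-patient processing notes.
#'
#' @param report a `cohort_report` from [run_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$displacements, file.path(dir, "displacements.csv"),
                   row.names = FALSE)
  json <- report
  json$measurements <- NULL
  json$displacements <- NULL
  json$log <- NULL
  jsonlite::write_json(rapply(unclass(json), unclass, how = "replace"),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(format_report_text(report), file.path(dir, "report.txt"))
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

format_report_text <- function(r) {
  out <- c(sprintf("Cohort report (n = %d patients, alpha = %g)",
                   r$n_patients, r$alpha), "")
  if (length(r$failed))
    out <- c(out, paste("PARTIAL: failed patients:",
                        paste(r$failed, collapse = ", ")), "")
  out <- c(out, "Reference point positions (distance to origin):")
  for (p in r$positions)
    out <- c(out, sprintf("  %-4s %-14s %s mm  (%s)", p$stage, p$point,
                          fmt_ms(p$mean_mm, p$sd_mm), p$modal_direction))
  out <- c(out, "", "Movement with reduction (post - pre):")
  for (p in r$displacement_summary)
    out <- c(out, sprintf("  %-14s %s mm  (%s)", p$point,
                          fmt_ms(p$mean_mm, p$sd_mm), p$modal_direction))
  out <- c(out, "", sprintf("Displacement direction counts: dorsal %d, palmar %d, neutral %d",
                            r$counts$dorsal, r$counts$palmar, r$counts$neutral))
  f <- r$stats$friedman
  if (inherits(f, "stat_result"))
    out <- c(out, "", sprintf(
      "Friedman test on movement distances: chi2 = %.2f, df = %d, p = %.4g",
      f$statistic, f$df, f$p_value))
  ph <- r$stats$posthoc
  if (is.data.frame(ph)) {
    out <- c(out, "Scheffe-type post-hoc:")
    for (i in seq_len(nrow(ph)))
      out <- c(out, sprintf("  %s vs %s: chi2 = %.2f, p = %.4g%s",
                            ph$treatment_i[i], ph$treatment_j[i],
                            ph$statistic[i], ph$p_value[i],
                            if (ph$significant[i]) "  *" else ""))
  }
  aw <- r$stats$area_wilcoxon
  out <- c(out, "", if (inherits(aw, "stat_result"))
    sprintf("Plane area pre vs post (Wilcoxon signed-rank): V = %g, p = %.4g",
            aw$statistic, aw$p_value)
    else paste("Plane area pre vs post:", aw))
  for (nm in names(r$stats$pearson)) {
    p <- r$stats$pearson[[nm]]
    if (inherits(p, "stat_result"))
      out <- c(out, sprintf("Pearson 3D vs 2D %s: r = %.2f, p = %.4g",
                            toupper(nm), p$statistic, p$p_value))
  }
  if (!is.null(r$stats$icc))
    for (nm in names(r$stats$icc)) {
      x <- r$stats$icc[[nm]]
      if (inherits(x, "stat_result"))
        out <- c(out, sprintf("ICC(2,1) %s (two raters): %.2f", toupper(nm),
                              x$statistic))
    }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
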