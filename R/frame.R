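#' Axis line in lab coordinates
#'
#' A straight line given by an anchor point and a unit direction, used for the
#' long axis of the radius shaft.
#'
#' @param anchor point on the line (length-3, mm, lab coordinates).
#' @param direction direction vector (normalised internally).
#' @return object of class `axis_line` with fields `anchor` and `direction`
#'   (unit norm to within 1e-12).
#' @export
axis_line <- function(anchor, direction) {
  structure(list(anchor = vec3(anchor, "anchor"),
                 direction = unit3(vec3(direction, "direction"))),
            class = "axis_line")
}

#' Fit the long axis of the radius shaft to a point cloud
#'
#' Estimates the long axis from surface points of the intact distal radius
#' shaft. Two fitting strategies are available:
#'
#' * `"pca_centroids"` (default): an initial principal axis is computed from
#'   the whole cloud, points are binned into slabs of thickness `slab_mm`
#'   along it, and the returned axis is the principal axis of the per-slab
#'   cross-section centroids. Cross-section centroids sit on the true axis of
#'   a tubular shaft regardless of its flaring radius, which makes this
#'   robust to the distal flare of the radius.
#' * `"cylinder_lsq"`: least-squares cylinder fit, minimising the variance of
#'   the point-to-axis distances over axis direction and position,
#'   initialised from the centroid-PCA estimate.
#'
#' The fitted direction is sign-ambiguous; when `distal_ref` is supplied the
#' direction is flipped, if needed, to point away from it, i.e. proximally
#' (the anatomical convention is proximal = positive y).
#'
#' @param points n x 3 matrix of lab-coordinate points (mm), n >= 10, spanning
#'   at least 5 mm along their principal direction.
#' @param method `"pca_centroids"` or `"cylinder_lsq"`.
#' @param distal_ref optional point on the distal side of the shaft used to
#'   orient the axis proximally.
#' @param slab_mm slab thickness for the centroid method (mm).
#' @return an [axis_line()].
#' @export
fit_long_axis <- function(points,
                          method = c("pca_centroids", "cylinder_lsq"),
                          distal_ref = NULL, slab_mm = 2) {
  method <- match.arg(method)
  p <- as_points(points)
  if (nrow(p) < 10L)
    stop("need at least 10 shaft points; got ", nrow(p))

  ctr <- colMeans(p)
  pc <- sweep(p, 2L, ctr)
  sv <- svd(pc, nu = 0L)
  if (diff(range(pc %*% sv$v[, 1L])) < 5)
    stop("point cloud spans < 5 mm along its principal direction")
  if (sv$d[1L] < 1.2 * sv$d[2L])
    stop("degenerate (near-isotropic) point cloud: no dominant axis")
  u0 <- sv$v[, 1L]

  # per-slab cross-section centroids along the provisional axis
  t0 <- drop(pc %*% u0)
  slab <- floor((t0 - min(t0)) / slab_mm)
  cents <- rowsum(p, slab) / as.vector(table(slab))
  if (nrow(cents) >= 3L) {
    cc <- sweep(cents, 2L, colMeans(cents))
    u <- svd(cc, nu = 0L)$v[, 1L]
    anchor <- colMeans(cents)
  } else {
    u <- u0
    anchor <- ctr
  }

  if (method == "cylinder_lsq") {
    # parametrise direction by spherical angles and the anchor by an in-plane
    # offset; minimise the variance of radial distances (cylinderness)
    th0 <- acos(pmin(1, pmax(-1, u[3L])))
    ph0 <- atan2(u[2L], u[1L])
    obj <- function(par) {
      d <- c(sin(par[1L]) * cos(par[2L]), sin(par[1L]) * sin(par[2L]),
             cos(par[1L]))
      b1 <- unit3(if (abs(d[1L]) < 0.9) cross3(d, c(1, 0, 0)) else
                    cross3(d, c(0, 1, 0)))
      b2 <- cross3(d, b1)
      a <- anchor + par[3L] * b1 + par[4L] * b2
      rel <- sweep(p, 2L, a)
      along <- drop(rel %*% d)
      r2 <- rowSums(rel^2) - along^2
      r <- sqrt(pmax(r2, 0))
      stats::var(r)
    }
    fit <- stats::optim(c(th0, ph0, 0, 0), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    u <- c(sin(fit$par[1L]) * cos(fit$par[2L]),
           sin(fit$par[1L]) * sin(fit$par[2L]), cos(fit$par[1L]))
    b1 <- unit3(if (abs(u[1L]) < 0.9) cross3(u, c(1, 0, 0)) else
                  cross3(u, c(0, 1, 0)))
    b2 <- cross3(u, b1)
    anchor <- anchor + fit$par[3L] * b1 + fit$par[4L] * b2
  }

  if (!is.null(distal_ref)) {
    dr <- vec3(distal_ref, "distal_ref")
    if (sum(u * (anchor - dr)) < 0) u <- -u
  }
  axis_line(anchor, u)
}

#' Anatomical coordinate frame of the distal radius
#'
#' Constructs the radius coordinate system: the y-axis is the shaft long axis
#' with proximal positive; the z-axis is the unit projection of the line from
#' the base of the ulnar sigmoid notch to the radial styloid process onto the
#' plane perpendicular to the y-axis (radial positive); the x-axis completes a
#' right-handed system (`ex = ey x ez`). For a right wrist +x points
#' dorsally; for a left wrist the same construction makes +x palmar, and all
#' anatomical direction labelling routes through the `side` field.
#'
#' @param long_axis [axis_line()] of the shaft, direction pointing proximally.
#' @param sigmoid_base lab point at the base of the ulnar sigmoid notch.
#' @param styloid lab point at the radial styloid process.
#' @param origin lab point used as the frame origin (intersection of the joint
#'   surface and the long axis; see [locate_origin()]). Projected onto the
#'   axis if not already on it.
#' @param side `"right"` or `"left"`.
#' @return object of class `anatomical_frame` with fields `origin`, `ex`,
#'   `ey`, `ez`, `side`; axes are orthonormal and right-handed to 1e-9.
#' @export
build_frame <- function(long_axis, sigmoid_base, styloid, origin,
                        side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(inherits(long_axis, "axis_line"))
  ey <- long_axis$direction
  v <- vec3(styloid, "styloid") - vec3(sigmoid_base, "sigmoid_base")
  proj <- v - sum(v * ey) * ey
  if (norm3(proj) < 1e-6)
    stop("sigmoid_base -> styloid line is parallel to the long axis; ",
         "cannot orient the z-axis")
  ez <- proj / norm3(proj)
  ex <- cross3(ey, ez)
  o <- vec3(origin, "origin")
  o <- long_axis$anchor + sum((o - long_axis$anchor) * ey) * ey
  structure(list(origin = o, ex = ex, ey = ey, ez = ez, side = side),
            class = "anatomical_frame")
}

#' Locate the frame origin on the long axis
#'
#' Returns the intersection of the joint surface and the radius long axis:
#' the joint-surface point closest to the axis is found and orthogonally
#' projected onto it. A single manually picked intersection point is simply
#' projected onto the axis.
#'
#' @param long_axis [axis_line()].
#' @param joint_surface_points one point or an n x 3 matrix of joint-surface
#'   points (mm, lab coordinates); must be non-empty.
#' @return lab-coordinate point on the axis (length-3 vector).
#' @export
locate_origin <- function(long_axis, joint_surface_points) {
  stopifnot(inherits(long_axis, "axis_line"))
  p <- as_points(joint_surface_points, "joint_surface_points")
  if (nrow(p) == 0L) stop("joint_surface_points is empty")
  rel <- sweep(p, 2L, long_axis$anchor)
  along <- drop(rel %*% long_axis$direction)
  d2 <- rowSums(rel^2) - along^2
  i <- which.min(d2)
  long_axis$anchor + along[i] * long_axis$direction
}

#' Express lab-coordinate points in an anatomical frame
#'
#' Components of `lab_point - origin` along the frame axes. The map is an
#' isometry, so pairwise distances are preserved.
#'
#' @param frame an [build_frame()] result.
#' @param points point or n x 3 matrix in lab coordinates.
#' @return n x 3 matrix of frame-local coordinates
#'   (x dorsal/palmar, y proximal+, z radial+).
#' @export
to_frame <- function(frame, points) {
  stopifnot(inherits(frame, "anatomical_frame"))
  p <- as_points(points)
  B <- cbind(frame$ex, frame$ey, frame$ez)
  out <- sweep(p, 2L, frame$origin) %*% B
  colnames(out) <- c("x", "y", "z")
  out
}

#' Map frame-local points back to lab coordinates (inverse of [to_frame()])
#' @inheritParams to_frame
#' @return n x 3 matrix of lab coordinates.
#' @export
from_frame <- function(frame, points) {
  stopifnot(inherits(frame, "anatomical_frame"))
  p <- as_points(points)
  B <- cbind(frame$ex, frame$ey, frame$ez)
  out <- sweep(p %*% t(B), 2L, frame$origin, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>", x$side, "wrist\n")
  cat("  origin:", paste(sprintf("%.3f", x$origin), collapse = ", "), "mm\n")
  for (ax in c("ex", "ey", "ez"))
    cat(" ", ax, ":", paste(sprintf("%.6f", x[[ax]]), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise / deserialise an anatomical frame as JSON
#' @param frame an `anatomical_frame`.
#' @param path file path; for `frame_from_json` the file to read.
#' @return `frame_to_json` returns `path` invisibly; `frame_from_json` the frame.
#' @export
frame_to_json <- function(frame, path) {
  stopifnot(inherits(frame, "anatomical_frame"))
  jsonlite::write_json(unclass(frame), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname frame_to_json
#' @export
frame_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(origin = vec3(x$origin), ex = vec3(x$ex), ey = vec3(x$ey),
                 ez = vec3(x$ez), side = x$side),
            class = "anatomical_frame")
}
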