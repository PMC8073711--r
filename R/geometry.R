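#' @title Small 3D vector/matrix helpers
#' @description Internal linear-algebra primitives shared by the frame,
#'   indices and synthetic modules. Points are plain numeric length-3 vectors
#'   or n x 3 matrices, in millimetres.
#' @name geometry-helpers
#' @keywords internal
NULL

# coerce a single point or an n x 3 matrix/data.frame to an n x 3 numeric matrix
as_points <- function(x, arg = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != 3L)
      stop(sprintf("'%s' must be a length-3 point or an n x 3 matrix", arg))
    x <- matrix(as.numeric(x), nrow = 1L)
  }
  x <- matrix(as.numeric(x), nrow = nrow(x), ncol = 3L,
              dimnames = list(NULL, c("x", "y", "z")))
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite coordinates", arg))
  x
}

vec3 <- function(x, arg = "vector") {
  v <- as.numeric(x)
  if (length(v) != 3L || !all(is.finite(v)))
    stop(sprintf("'%s' must be a finite length-3 numeric vector", arg))
  unname(v)
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v, arg = "vector") {
  n <- norm3(v)
  if (n < 1e-12) stop(sprintf("cannot normalise near-zero '%s'", arg))
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#'
#' @param axis direction of the rotation axis (any nonzero length-3 vector).
#' @param angle_deg rotation angle in degrees, right-hand rule about `axis`.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rotation_about <- function(axis, angle_deg) {
  u <- unit3(vec3(axis, "axis"))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid (proper orthogonal) transform
#'
#' A rotation plus translation mapping lab coordinates to lab coordinates:
#' `p -> rotation %*% p + translation`.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector, millimetres.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- vec3(translation, "translation")
  err_orth <- max(abs(crossprod(rotation) - diag(3)))
  if (err_orth > 1e-9)
    stop("rotation is not orthonormal (max |R'R - I| = ", format(err_orth), ")")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1); got det = ", format(det(rotation)))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param tf a [rigid_transform()].
#' @param points a point or n x 3 matrix.
#' @return transformed points, same shape as input (always n x 3 matrix).
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  p <- as_points(points)
  out <- sweep(p %*% t(tf$rotation), 2L, tf$translation, "+")
  dimnames(out) <- dimnames(p)
  out
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -drop(Rt %*% tf$translation))
}

#' Compose rigid transforms (apply `b` first, then `a`)
#' @param a,b [rigid_transform()] objects.
#' @return the composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

# uniform-ish random rotation from three random Euler-style rotations;
# uses the current RNG stream
random_rotation <- function() {
  rotation_about(c(1, 0, 0), stats::runif(1, 0, 360)) %*%
    rotation_about(c(0, 1, 0), stats::runif(1, 0, 360)) %*%
    rotation_about(c(0, 0, 1), stats::runif(1, 0, 360))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat("<rigid_transform> rotation", sprintf("%.3f", ang), "deg, translation (",
      paste(sprintf("%.3f", x$translation), collapse = ", "), ") mm\n")
  if (!is.null(attr(x, "rms")))
    cat("  ICP: rms =", format(attr(x, "rms")), "mm in",
        attr(x, "iterations"), "iterations; converged =",
        attr(x, "converged"), "\n")
  invisible(x)
}
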