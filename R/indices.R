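#' Reference-point triad of the distal radius
#'
#' The three measurement landmarks expressed in the anatomical frame:
#' (1) the radial styloid process, (2) the sigmoid notch volar edge and
#' (3) the sigmoid notch dorsal edge. Points must be pairwise distinct
#' (> 1e-6 mm apart); collinear triads are accepted but flagged degenerate by
#' the area computation.
#'
#' @param styloid,sigmoid_volar,sigmoid_dorsal frame-coordinate points
#'   (length-3, mm: x dorsal/palmar, y proximal+, z radial+).
#' @return object of class `reference_triad`: a 3 x 3 matrix with rows
#'   `styloid`, `sigmoid_volar`, `sigmoid_dorsal`.
#' @export
reference_triad <- function(styloid, sigmoid_volar, sigmoid_dorsal) {
  m <- rbind(vec3(styloid, "styloid"),
             vec3(sigmoid_volar, "sigmoid_volar"),
             vec3(sigmoid_dorsal, "sigmoid_dorsal"))
  dimnames(m) <- list(c("styloid", "sigmoid_volar", "sigmoid_dorsal"),
                      c("x", "y", "z"))
  d <- c(norm3(m[1L, ] - m[2L, ]), norm3(m[1L, ] - m[3L, ]),
         norm3(m[2L, ] - m[3L, ]))
  if (any(d <= 1e-6))
    stop("triad points must be pairwise distinct (> 1e-6 mm apart)")
  structure(m, class = c("reference_triad", "matrix"))
}

as_triad <- function(x) {
  if (inherits(x, "reference_triad")) return(x)
  p <- as_points(x, "triad")
  if (nrow(p) != 3L) stop("a triad needs exactly 3 points")
  reference_triad(p[1L, ], p[2L, ], p[3L, ])
}

#' Centroid (barycentre) of a reference triad
#'
#' Component-wise mean of the three reference points; the study's
#' "barycentric coordinate" of the plane connecting them.
#'
#' @param triad a [reference_triad()].
#' @return length-3 point, mm.
#' @export
triad_centroid <- function(triad) {
  colMeans(unclass(as_triad(triad)))
}

#' Area of the triangle spanned by a reference triad
#'
#' `0.5 * |(p2 - p1) x (p3 - p1)|`, in mm^2, used as a proxy for the
#' articular surface gap. Collinear triads return 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param triad a [reference_triad()].
#' @return scalar area (mm^2), with logical attribute `degenerate`.
#' @export
triad_area <- function(triad) {
  t3 <- as_triad(triad)
  a <- 0.5 * norm3(cross3(t3[2L, ] - t3[1L, ], t3[3L, ] - t3[1L, ]))
  # degenerate when the triangle height is negligible relative to its extent
  scale <- max(norm3(t3[2L, ] - t3[1L, ]), norm3(t3[3L, ] - t3[1L, ]))
  structure(a, degenerate = a <= 1e-9 * max(scale^2, 1))
}

signed_elevation <- function(dy, dacross, what) {
  if (abs(dy) < 1e-12 && abs(dacross) < 1e-12)
    stop("coincident projections: cannot measure ", what)
  atan2(dy, abs(dacross)) * 180 / pi
}

#' 3D volar tilt from a reference triad
#'
#' Signed angle, in the sagittal (x-y) plane of the anatomical frame, between
#' the projected line from the sigmoid volar edge (2) to the dorsal edge (3)
#' and the perpendicular to the long axis. Positive when the volar edge lies
#' distal to the dorsal edge (normal palmar tilt):
#' `atan2(y3 - y2, |x3 - x2|)`.
#'
#' @param triad a [reference_triad()].
#' @return angle in degrees, in \[-90, 90\].
#' @export
volar_tilt_3d <- function(triad) {
  t3 <- as_triad(triad)
  signed_elevation(t3["sigmoid_dorsal", "y"] - t3["sigmoid_volar", "y"],
                   t3["sigmoid_dorsal", "x"] - t3["sigmoid_volar", "x"],
                   "3D volar tilt")
}

#' 3D radial inclination from a reference triad
#'
#' Signed angle, in the coronal (y-z) plane, between the projected line from
#' the radial styloid (1) to the sigmoid volar edge (2) and the perpendicular
#' to the long axis. Positive when the styloid lies distal to the sigmoid
#' edge (normal inclination): `atan2(y2 - y1, |z2 - z1|)`.
#'
#' @param triad a [reference_triad()].
#' @return angle in degrees, in \[-90, 90\].
#' @export
radial_inclination_3d <- function(triad) {
  t3 <- as_triad(triad)
  signed_elevation(t3["sigmoid_volar", "y"] - t3["styloid", "y"],
                   t3["sigmoid_volar", "z"] - t3["styloid", "z"],
                   "3D radial inclination")
}

#' All scalar indices for one triad
#'
#' @param triad a [reference_triad()].
#' @return object of class `triad_indices`: list with `centroid` (mm),
#'   `area_mm2`, `vt_deg` (3D volar tilt), `ri_deg` (3D radial inclination).
#' @export
triad_indices <- function(triad) {
  t3 <- as_triad(triad)
  structure(list(centroid = triad_centroid(t3),
                 area_mm2 = as.numeric(triad_area(t3)),
                 vt_deg = volar_tilt_3d(t3),
                 ri_deg = radial_inclination_3d(t3)),
            class = "triad_indices")
}

#' Anatomical direction label of a displacement vector
#'
#' Maps the sign pattern of a frame-coordinate vector to the anatomical
#' vocabulary: +y "proximal" / -y "distal"; +z "radial" / -z "ulnar"; the x
#' component is "dorsal"/"palmar" for +/- on a right wrist and mirrored on a
#' left wrist. Components with absolute value below `dead_zone` are omitted;
#' an all-suppressed vector is labelled `"none"`. Terms are ordered
#' z-axis, x-axis, y-axis (e.g. "ulnar-palmar-distal").
#'
#' @param vector length-3 frame-coordinate vector (mm).
#' @param side `"right"` or `"left"`.
#' @param dead_zone magnitude (mm) below which a component is not named.
#' @return a single label string.
#' @export
direction_label <- function(vector, side = c("right", "left"), dead_zone = 0) {
  side <- match.arg(side)
  v <- vec3(vector, "vector")
  x_pos <- if (side == "right") "dorsal" else "palmar"
  x_neg <- if (side == "right") "palmar" else "dorsal"
  named <- function(val, pos, neg) {
    if (abs(val) < dead_zone || val == 0) NULL
    else if (val > 0) pos else neg
  }
  terms <- c(named(v[3L], "radial", "ulnar"),
             named(v[1L], x_pos, x_neg),
             named(v[2L], "proximal", "distal"))
  if (is.null(terms)) "none" else paste(terms, collapse = "-")
}

#' Displacement of a triad between two stages
#'
#' Per-point and centroid movement vectors `post - pre` between two triads
#' expressed in the same anatomical frame, with Euclidean magnitudes and
#' anatomical direction labels. The centroid vector is, exactly, the
#' arithmetic mean of the three per-point vectors.
#'
#' @param pre,post [reference_triad()] objects in one common frame.
#' @param side `"right"` or `"left"` (routes the x-axis label).
#' @param dead_zone passed to [direction_label()].
#' @param frame_id_pre,frame_id_post optional identifiers; an error is raised
#'   if both are supplied and differ.
#' @return object of class `displacement_record`: list with `vectors`
#'   (4 x 3 matrix, rows styloid/sigmoid_volar/sigmoid_dorsal/centroid),
#'   `magnitudes_mm`, and `labels`.
#' @export
displacement <- function(pre, post, side = c("right", "left"), dead_zone = 0,
                         frame_id_pre = NULL, frame_id_post = NULL) {
  side <- match.arg(side)
  if (!is.null(frame_id_pre) && !is.null(frame_id_post) &&
      !identical(frame_id_pre, frame_id_post))
    stop("pre and post triads are in different frames: ",
         frame_id_pre, " vs ", frame_id_post)
  a <- as_triad(pre)
  b <- as_triad(post)
  v <- unclass(b) - unclass(a)
  v <- rbind(v, centroid = colMeans(v))
  mag <- sqrt(rowSums(v^2))
  lab <- vapply(seq_len(4L),
                function(i) direction_label(v[i, ], side, dead_zone),
                character(1L))
  names(lab) <- rownames(v)
  structure(list(vectors = v, magnitudes_mm = mag, labels = lab, side = side),
            class = "displacement_record")
}

#' @export
print.displacement_record <- function(x, ...) {
  cat("<displacement_record> (post - pre,", x$side, "wrist)\n")
  for (nm in rownames(x$vectors))
    cat(sprintf("  %-14s %6.2f mm  %s\n", nm, x$magnitudes_mm[[nm]],
                x$labels[[nm]]))
  invisible(x)
}

#' 2D radiograph-plane volar tilt and radial inclination
#'
#' The same signed-elevation computation as the 3D indices, restricted to a
#' radiograph plane whose vertical axis is the radius long axis (proximal
#' positive y); also usable on orthographic projections of 3D landmarks to
#' simulate radiographic measurement. `vt_2d` takes the volar and dorsal edge
#' of the radius on the lateral view (positive = volar edge distal);
#' `ri_2d` takes the styloid tip and the ulnar aspect of the distal radius on
#' the postero-anterior view (positive = styloid distal).
#'
#' @param volar_edge,dorsal_edge,styloid,ulnar_aspect length-2 points
#'   `(across, along-axis)` in mm.
#' @return angle in degrees, in \[-90, 90\].
#' @export
vt_2d <- function(volar_edge, dorsal_edge) {
  v <- as.numeric(volar_edge)
  d <- as.numeric(dorsal_edge)
  stopifnot(length(v) == 2L, length(d) == 2L)
  signed_elevation(d[2L] - v[2L], d[1L] - v[1L], "2D volar tilt")
}

#' @rdname vt_2d
#' @export
ri_2d <- function(styloid, ulnar_aspect) {
  s <- as.numeric(styloid)
  u <- as.numeric(ulnar_aspect)
  stopifnot(length(s) == 2L, length(u) == 2L)
  signed_elevation(u[2L] - s[2L], u[1L] - s[1L], "2D radial inclination")
}
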