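#' Read vertices from an ASCII STL or PLY file
#'
#' Minimal readers for the two surface formats used for shaft geometry; only
#' the vertex coordinates are used (the pipeline consumes meshes as point
#' clouds, in mm). STL: every `vertex x y z` line is collected and duplicate
#' vertices shared between facets are dropped. PLY: ASCII format only, the
#' leading x/y/z properties of each vertex element row are read.
#'
#' @param path file path.
#' @return n x 3 numeric matrix of unique vertex coordinates.
#' @export
read_mesh_points <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\\s*ply\\s*$", head, ignore.case = TRUE))
    read_ply_points(path)
  else if (grepl("^\\s*solid", head, ignore.case = TRUE))
    read_stl_points(path)
  else stop("unrecognised mesh format (expect ASCII STL or PLY): ", path)
}

#' @rdname read_mesh_points
#' @export
read_stl_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertex records in STL file: ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  m <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3L)))
  if (anyNA(m)) stop("non-numeric vertex coordinates in STL file: ", path)
  unique(m)
}

#' @rdname read_mesh_points
#' @export
read_ply_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("malformed PLY (no end_header): ", path)
  hdr <- trimws(lines[seq_len(end_hdr)])
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  el <- grep("^element\\s", hdr, value = TRUE)
  counts <- as.integer(sub("^element\\s+\\S+\\s+(\\d+)$", "\\1", el))
  names(counts) <- sub("^element\\s+(\\S+)\\s+\\d+$", "\\1", el)
  nv <- counts[["vertex"]]
  if (is.null(nv) || is.na(nv)) stop("no vertex element in PLY header: ", path)
  body <- lines[(end_hdr + 1L):(end_hdr + nv)]
  toks <- strsplit(trimws(body), "\\s+")
  m <- t(vapply(toks, function(t) as.numeric(t[1:3]), numeric(3L)))
  if (anyNA(m)) stop("non-numeric vertex coordinates in PLY file: ", path)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a point cloud as ASCII PLY
#'
#' @param points n x 3 matrix of coordinates, mm.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ply_points <- function(points, path) {
  p <- as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(p)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(apply(p, 1L, function(v)
    paste(format(v, trim = TRUE, digits = 10), collapse = " ")), con)
  invisible(path)
}
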