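LANDMARK_LABELS <- c("styloid", "sigmoid_volar", "sigmoid_dorsal",
                     "sigmoid_base", "origin")

#' Read per-patient landmark coordinates
#'
#' Reads the landmark table dialect used throughout the package: CSV with
#' header `patient_id,stage,label,x,y,z` (optional `side` column), one row
#' per landmark, coordinates in mm (lab coordinates); `stage` is `pre` or
#' `post`, `label` one of `styloid`, `sigmoid_volar`, `sigmoid_dorsal`,
#' `sigmoid_base`, `origin`. A JSON array of objects with the same fields is
#' accepted. Validation reports the offending patient, stage, label and file
#' line for duplicate labels, unknown stages/labels and non-numeric
#' coordinates; missing required labels are reported per patient/stage.
#'
#' @param path CSV or JSON file path.
#' @param require_complete require all five labels for both stages of every
#'   patient (default TRUE).
#' @return data.frame `patient_id, stage, label, x, y, z, side` (side
#'   defaults to `"right"`), ordered by patient, stage, label.
#' @export
read_landmarks <- function(path, require_complete = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    line_no <- seq_len(nrow(df))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  }
  need <- c("patient_id", "stage", "label", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("landmark file missing column(s): ", paste(miss, collapse = ", "))
  if (!"side" %in% names(df)) df$side <- "right"
  df$side[is.na(df$side) | df$side == ""] <- "right"

  bad <- character()
  for (col in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    nn <- which(is.na(v) & !is.na(df[[col]]))
    if (length(nn))
      bad <- c(bad, sprintf(
        "line %d (patient %s, stage %s, label %s): non-numeric %s '%s'",
        line_no[nn], df$patient_id[nn], df$stage[nn], df$label[nn], col,
        df[[col]][nn]))
    df[[col]] <- v
  }
  st_bad <- which(!df$stage %in% c("pre", "post"))
  if (length(st_bad))
    bad <- c(bad, sprintf("line %d (patient %s): unknown stage '%s'",
                          line_no[st_bad], df$patient_id[st_bad],
                          df$stage[st_bad]))
  lb_bad <- which(!df$label %in% LANDMARK_LABELS)
  if (length(lb_bad))
    bad <- c(bad, sprintf("line %d (patient %s, stage %s): unknown label '%s'",
                          line_no[lb_bad], df$patient_id[lb_bad],
                          df$stage[lb_bad], df$label[lb_bad]))
  key <- paste(df$patient_id, df$stage, df$label)
  dup <- which(duplicated(key))
  if (length(dup))
    bad <- c(bad, sprintf(
      "line %d: duplicate label (patient %s, stage %s, label %s)",
      line_no[dup], df$patient_id[dup], df$stage[dup], df$label[dup]))
  sd_bad <- which(!df$side %in% c("right", "left"))
  if (length(sd_bad))
    bad <- c(bad, sprintf("line %d (patient %s): unknown side '%s'",
                          line_no[sd_bad], df$patient_id[sd_bad],
                          df$side[sd_bad]))
  if (length(bad))
    stop("invalid landmark file ", path, ":\n  ",
         paste(bad, collapse = "\n  "))

  if (require_complete) {
    missing_msgs <- character()
    for (pid in unique(df$patient_id)) for (st in c("pre", "post")) {
      have <- df$label[df$patient_id == pid & df$stage == st]
      lack <- setdiff(LANDMARK_LABELS, have)
      if (length(lack))
        missing_msgs <- c(missing_msgs, sprintf(
          "patient %s stage %s: missing label(s) %s", pid, st,
          paste(lack, collapse = ", ")))
    }
    if (length(missing_msgs))
      stop("incomplete landmark file ", path, ":\n  ",
           paste(missing_msgs, collapse = "\n  "))
  }
  df <- df[order(df$patient_id, df$stage, match(df$label, LANDMARK_LABELS)), ]
  rownames(df) <- NULL
  df[c("patient_id", "stage", "label", "x", "y", "z", "side")]
}

#' Write a landmark table in the canonical dialect
#'
#' Inverse of [read_landmarks()]: `write_landmarks` then `read_landmarks`
#' reproduces the table (round-trip stable on canonical form).
#'
#' @param landmarks data.frame as returned by [read_landmarks()].
#' @param path output path; `.json` extension selects JSON, otherwise CSV.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- landmarks[c("patient_id", "stage", "label", "x", "y", "z", "side")]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  else
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
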