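#' Per-frame detection stream
#'
#' A `frame_stream` is the tracker's input container: an ordered set of
#' per-frame detections plus the video frame rate. Internally it is a
#' data frame with one row per detection and columns
#' `frame, x1, y1, x2, y2, score, cls`. Frame indices are 1-based (the
#' MOT-Challenge on-disk convention); timestamps are `frame / fps` seconds.
#'
#' @param det A data frame with columns `frame, x1, y1, x2, y2, score, cls`
#'   (may have zero rows).
#' @param fps Frames per second, a positive real. The source videos' frame
#'   rate is detector metadata the caller must supply; it is never
#'   defaulted silently.
#' @return An object of class `frame_stream` with elements `det` and `fps`.
#' @export
frame_stream <- function(det = empty_detections(), fps) {
  stopifnot_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  need <- c("frame", "x1", "y1", "x2", "y2", "score", "cls")
  if (!is.data.frame(det) || !all(need %in% names(det)))
    pt_validation_error(paste("detections need columns:",
                              paste(need, collapse = ", ")))
  det <- det[, need, drop = FALSE]
  if (nrow(det)) {
    if (any(det$frame < 0) || any(det$frame != floor(det$frame)))
      pt_validation_error("frame indices must be non-negative integers")
    if (any(det$score < 0 | det$score > 1))
      pt_validation_error("detection scores must lie in [0, 1]")
    if (!all(det$cls %in% pt_classes()))
      pt_validation_error(paste("unknown class; expected one of:",
                                paste(pt_classes(), collapse = ", ")))
    if (any(det$x2 <= det$x1) || any(det$y2 <= det$y1))
      pt_validation_error("all boxes must have positive width and height")
    det <- det[order(det$frame), , drop = FALSE]
    rownames(det) <- NULL
  }
  structure(list(det = det, fps = fps), class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat(sprintf("<frame_stream> %d detections over %d frames @ %g fps\n",
              nrow(x$det), length(unique(x$det$frame)), x$fps))
  invisible(x)
}

# The closed two-class vocabulary: '0' is an individual pig, '1' is a box
# around an ongoing fight.
pt_classes <- function() c("pig", "pig_fighting")

pt_class_code <- function(cls) match(cls, pt_classes()) - 1L

empty_detections <- function() {
  data.frame(frame = integer(0), x1 = numeric(0), y1 = numeric(0),
             x2 = numeric(0), y2 = numeric(0), score = numeric(0),
             cls = character(0), stringsAsFactors = FALSE)
}

#' Subset a stream
#'
#' @param stream A [frame_stream()].
#' @param cls Optional class to keep.
#' @param frame Optional frame index to keep.
#' @return A data frame of detections.
#' @export
stream_detections <- function(stream, cls = NULL, frame = NULL) {
  det <- stream$det
  if (!is.null(cls)) det <- det[det$cls == cls, , drop = FALSE]
  if (!is.null(frame)) det <- det[det$frame == frame, , drop = FALSE]
  det
}

#' Persistent identity: one track's boxes over time
#'
#' A `track_record` holds a tracked identity: its positive integer id, its
#' class, and one scored box per frame it was observed in. Frames within a
#' record are strictly increasing; gaps (frames with no box) are allowed
#' and arise when a track survives occlusion.
#'
#' @param track_id Positive integer identity.
#' @param cls Class, one of `"pig"` or `"pig_fighting"`.
#' @param boxes Data frame with columns `frame, x1, y1, x2, y2, score`.
#' @return An object of class `track_record`.
#' @export
track_record <- function(track_id, cls, boxes) {
  if (!is.numeric(track_id) || length(track_id) != 1L || track_id < 1 ||
      track_id != floor(track_id))
    pt_validation_error("track_id must be a positive integer")
  if (!cls %in% pt_classes())
    pt_validation_error(paste("unknown class:", cls))
  need <- c("frame", "x1", "y1", "x2", "y2", "score")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    pt_validation_error(paste("track boxes need columns:",
                              paste(need, collapse = ", ")))
  boxes <- boxes[order(boxes$frame), need, drop = FALSE]
  if (anyDuplicated(boxes$frame))
    pt_validation_error(sprintf(
      "track %d has more than one box in a frame", track_id))
  rownames(boxes) <- NULL
  structure(list(track_id = as.integer(track_id), cls = cls, boxes = boxes),
            class = "track_record")
}

#' @export
print.track_record <- function(x, ...) {
  cat(sprintf("<track_record> id %d (%s), %d boxes, frames [%s, %s]\n",
              x$track_id, x$cls, nrow(x$boxes),
              if (nrow(x$boxes)) min(x$boxes$frame) else NA,
              if (nrow(x$boxes)) max(x$boxes$frame) else NA))
  invisible(x)
}

# ---------------------------------------------------------------------------
# MOT-Challenge CSV dialects.
#
# Both the detection ("det") and the result ("track") dialects share the row
# layout
#   frame, id, bb_left, bb_top, bb_width, bb_height, conf, class, visibility
# with no header, UTF-8, '.' decimal separator. Raw detections carry id -1;
# tracker results carry real positive ids. Class codes: 0 = pig,
# 1 = pig_fighting.
# ---------------------------------------------------------------------------

parse_mot_rows <- function(path) {
  if (!file.exists(path))
    pt_missing_input(paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) && grepl("^\\s*frame", lines[1L], ignore.case = TRUE)) {
    lines <- lines[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(lines)) return(NULL)
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    pt_parse_error(sprintf("line %d: expected 9 comma-separated fields, got %d",
                           lineno[which(nf != 9L)[1L]], nf[nf != 9L][1L]))
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                               ncol = 9L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    pt_parse_error(sprintf("line %d: non-numeric field", lineno[bad]))
  }
  colnames(m) <- c("frame", "id", "bb_left", "bb_top", "bb_width",
                   "bb_height", "conf", "class", "visibility")
  list(m = m, lineno = lineno)
}

mot_matrix_to_detections <- function(m, lineno) {
  bad <- which(m[, "bb_width"] <= 0 | m[, "bb_height"] <= 0)
  if (length(bad))
    pt_parse_error(sprintf(
      "line %d: non-positive box width/height", lineno[bad[1L]]))
  if (any(!m[, "class"] %in% c(0, 1)))
    pt_validation_error(sprintf(
      "line %d: unknown class code %g (expected 0 = pig, 1 = pig_fighting)",
      lineno[which(!m[, "class"] %in% c(0, 1))[1L]],
      m[!m[, "class"] %in% c(0, 1), "class"][1L]))
  if (any(m[, "conf"] < 0 | m[, "conf"] > 1))
    pt_validation_error(sprintf(
      "line %d: confidence outside [0, 1]",
      lineno[which(m[, "conf"] < 0 | m[, "conf"] > 1)[1L]]))
  data.frame(
    frame = as.integer(m[, "frame"]),
    id = as.integer(m[, "id"]),
    x1 = m[, "bb_left"],
    y1 = m[, "bb_top"],
    x2 = m[, "bb_left"] + m[, "bb_width"],
    y2 = m[, "bb_top"] + m[, "bb_height"],
    score = m[, "conf"],
    cls = pt_classes()[as.integer(m[, "class"]) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Read raw detections from a MOT-Challenge CSV
#'
#' Rows are `frame, id, bb_left, bb_top, bb_width, bb_height, conf, class,
#' visibility` with `id = -1` for raw detections. Width/height boxes are
#' converted to corner form (`x2 = left + width`, `y2 = top + height`).
#' Rows with non-positive width or height are rejected with a parse error
#' naming the line; unknown class codes raise a validation error. An empty
#' file yields an empty stream, which is not an error.
#'
#' @param path Path to the CSV file.
#' @param fps Frames per second of the source video (required; the toolkit
#'   never guesses it).
#' @return A [frame_stream()].
#' @export
read_mot_detections <- function(path, fps) {
  parsed <- parse_mot_rows(path)
  if (is.null(parsed)) return(frame_stream(empty_detections(), fps))
  det <- mot_matrix_to_detections(parsed$m, parsed$lineno)
  det$id <- NULL
  frame_stream(det, fps)
}

#' Write tracker results as a MOT-Challenge CSV
#'
#' One row per `(frame, id)` with corner boxes converted back to
#' left/top/width/height, coordinates and confidences printed with two
#' decimal places (the round-trip contract), rows sorted by `(frame, id)`,
#' no header. An empty track list produces an empty file.
#'
#' @param tracks A list of [track_record()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mot_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    if (!inherits(tr, "track_record"))
      pt_validation_error("write_mot_tracks expects track_record objects")
    b <- tr$boxes
    if (!nrow(b)) return(NULL)
    data.frame(frame = b$frame, id = tr$track_id,
               bb_left = b$x1, bb_top = b$y1,
               bb_width = b$x2 - b$x1, bb_height = b$y2 - b$y1,
               conf = b$score, class = pt_class_code(tr$cls),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (anyDuplicated(df[, c("frame", "id")]))
    pt_validation_error("duplicate (frame, id) pair across track records")
  df <- df[order(df$frame, df$id), , drop = FALSE]
  lines <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%.2f,%d,1",
                   df$frame, df$id, df$bb_left, df$bb_top,
                   df$bb_width, df$bb_height, df$conf, df$class)
  writeLines(lines, path)
  invisible(path)
}

#' Read tracker results from a MOT-Challenge CSV
#'
#' Inverse of [write_mot_tracks()]: groups rows by id into
#' [track_record()]s. Every id must be positive and class-pure.
#'
#' @param path Path to the CSV file.
#' @return A list of [track_record()]s ordered by track id.
#' @export
read_mot_tracks <- function(path) {
  parsed <- parse_mot_rows(path)
  if (is.null(parsed)) return(list())
  det <- mot_matrix_to_detections(parsed$m, parsed$lineno)
  if (any(det$id < 1))
    pt_validation_error("track files must carry positive ids")
  ids <- sort(unique(det$id))
  lapply(ids, function(i) {
    rows <- det[det$id == i, , drop = FALSE]
    cls <- unique(rows$cls)
    if (length(cls) != 1L)
      pt_validation_error(sprintf("track %d mixes classes", i))
    track_record(i, cls,
                 rows[, c("frame", "x1", "y1", "x2", "y2", "score")])
  })
}
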