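#' Axis-aligned bounding box in corner form
#'
#' Boxes use continuous pixel coordinates with the origin at the top-left
#' corner, x growing rightward and y growing downward. Corner form means
#' `(x1, y1)` is the top-left and `(x2, y2)` the bottom-right corner, with
#' `x2 > x1`, `y2 > y1` and therefore strictly positive area. No `+1` pixel
#' correction is applied anywhere: geometry is continuous.
#'
#' @param x1,y1,x2,y2 Corner coordinates (numeric scalars).
#' @return A named numeric vector of length 4 with class `pt_box`.
#' @examples
#' b <- box(0, 0, 10, 20)
#' box_area(b)    # 200
#' box_center(b)  # c(5, 10)
#' @export
box <- function(x1, y1, x2, y2) {
  v <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  if (anyNA(v) || any(!is.finite(v)))
    pt_validation_error("box coordinates must be finite")
  if (v[["x2"]] <= v[["x1"]] || v[["y2"]] <= v[["y1"]])
    pt_validation_error(sprintf(
      "degenerate box (%g,%g,%g,%g): need x2 > x1 and y2 > y1",
      v[["x1"]], v[["y1"]], v[["x2"]], v[["y2"]]))
  class(v) <- "pt_box"
  v
}

#' @rdname box
#' @param b A box.
#' @export
box_area <- function(b) {
  unname((b[["x2"]] - b[["x1"]]) * (b[["y2"]] - b[["y1"]]))
}

#' @rdname box
#' @export
box_center <- function(b) {
  c(x = (b[["x1"]] + b[["x2"]]) / 2, y = (b[["y1"]] + b[["y2"]]) / 2)
}

#' @rdname box
#' @param a A second box.
#' @export
box_union <- function(a, b) {
  box(min(a[["x1"]], b[["x1"]]), min(a[["y1"]], b[["y1"]]),
      max(a[["x2"]], b[["x2"]]), max(a[["y2"]], b[["y2"]]))
}

#' Intersection over union of two boxes
#'
#' The overlap statistic used both for track-detection matching and for
#' true-positive decisions in detection evaluation: the intersection area
#' divided by the union area (area of the first plus area of the second
#' minus the intersection). Disjoint or merely corner/edge-touching boxes
#' score 0; identical boxes score 1.
#'
#' @param a,b Boxes (see [box()]), or plain numeric `(x1, y1, x2, y2)`
#'   vectors.
#' @return A fraction in `[0, 1]`.
#' @examples
#' box_iou(box(0, 0, 2, 2), box(1, 1, 3, 3))  # 1/7
#' @export
box_iou <- function(a, b) {
  iw <- min(a[["x2"]], b[["x2"]]) - max(a[["x1"]], b[["x1"]])
  ih <- min(a[["y2"]], b[["y2"]]) - max(a[["y1"]], b[["y1"]])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Pairwise IoU matrix
#'
#' @param a An `n x 4` matrix of boxes in corner form (one box per row).
#' @param b An `m x 4` matrix of boxes.
#' @return An `n x m` matrix of IoU values.
#' @export
iou_matrix <- function(a, b) {
  a <- as_box_matrix(a)
  b <- as_box_matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  ix1 <- outer(a[, 1L], b[, 1L], pmax)
  iy1 <- outer(a[, 2L], b[, 2L], pmax)
  ix2 <- outer(a[, 3L], b[, 3L], pmin)
  iy2 <- outer(a[, 4L], b[, 4L], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  inter / (outer(area_a, area_b, `+`) - inter)
}

# Accepts a pt_box, a length-4 vector, a data.frame with x1..y2 columns, or
# an n x 4 matrix; returns an n x 4 numeric matrix.
as_box_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[, c("x1", "y1", "x2", "y2"), drop = FALSE])
  } else if (is.null(dim(x))) {
    if (length(x) == 0L) return(matrix(numeric(0), 0L, 4L))
    x <- matrix(as.numeric(x), ncol = 4L, byrow = TRUE)
  }
  storage.mode(x) <- "double"
  unname(x[, 1:4, drop = FALSE])
}
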