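# Detection evaluation: greedy confidence-ordered matching, cumulative
# precision/recall, all-point-interpolated average precision and its mean
# over classes (mAP at a fixed IoU threshold).

#' Match predictions to ground truth boxes
#'
#' Greedy confidence-ordered one-to-one matching: predictions are visited
#' in descending score (ties broken by input order); a prediction is a
#' true positive if its best-IoU *unmatched* ground truth reaches
#' `iou_thresh`, and that ground truth is then consumed; otherwise it is a
#' false positive. False negatives are the ground truths never matched.
#'
#' @param scores Prediction confidences in `[0, 1]`.
#' @param pred_boxes Prediction boxes, `n x 4` matrix / data frame with
#'   `x1, y1, x2, y2` columns (all predictions of one class).
#' @param gt_boxes Ground-truth boxes of the same class (may be empty:
#'   then every prediction is a false positive).
#' @return An object of class `match_flags`: a list with `score` (sorted
#'   non-increasing), `is_tp` (logical, parallel to `score`) and `n_gt`.
#' @export
match_detections <- function(scores, pred_boxes, gt_boxes, iou_thresh = 0.5) {
  stopifnot_scalar_num(iou_thresh, "iou_thresh", lower = 0, upper = 1,
                       strict_lower = TRUE)
  pred <- as_box_matrix(pred_boxes)
  gt <- as_box_matrix(gt_boxes)
  if (length(scores) != nrow(pred))
    pt_validation_error("scores and pred_boxes disagree in length")
  ord <- order(-scores)   # stable: ties keep input order
  pred <- pred[ord, , drop = FALSE]
  scores <- scores[ord]
  n <- nrow(pred)
  is_tp <- logical(n)
  if (n && nrow(gt)) {
    iou <- iou_matrix(pred, gt)
    taken <- logical(nrow(gt))
    for (k in seq_len(n)) {
      cand <- which(!taken)
      if (!length(cand)) break
      best <- cand[which.max(iou[k, cand])]
      if (iou[k, best] >= iou_thresh) {
        is_tp[k] <- TRUE
        taken[best] <- TRUE
      }
    }
  }
  structure(list(score = as.numeric(scores), is_tp = is_tp,
                 n_gt = nrow(gt)),
            class = "match_flags")
}

# Pool flags from several images/frames; scores are re-sorted globally.
pool_match_flags <- function(flag_list) {
  score <- unlist(lapply(flag_list, `[[`, "score"))
  is_tp <- unlist(lapply(flag_list, `[[`, "is_tp"))
  n_gt <- sum(vapply(flag_list, `[[`, integer(1), "n_gt"))
  ord <- order(-score)
  structure(list(score = score[ord], is_tp = as.logical(is_tp[ord]),
                 n_gt = n_gt),
            class = "match_flags")
}

#' Cumulative precision-recall curve
#'
#' Walking down the score-ranked detections, after the k-th one
#' `precision = TP_k / (TP_k + FP_k)` and `recall = TP_k / n_gt`, where
#' `n_gt = TP + FN` is the ground-truth count. Recall is non-decreasing
#' along the curve.
#'
#' @param flags A `match_flags` object from [match_detections()].
#' @return An object of class `pr_curve`: a data frame with columns
#'   `recall` and `precision`.
#' @export
precision_recall <- function(flags) {
  if (!inherits(flags, "match_flags"))
    pt_validation_error("precision_recall expects a match_flags object")
  if (flags$n_gt == 0L)
    pt_evaluation_error("recall undefined: no ground-truth boxes")
  tp <- cumsum(flags$is_tp)
  k <- seq_along(flags$is_tp)
  curve <- data.frame(recall = tp / flags$n_gt, precision = tp / k)
  class(curve) <- c("pr_curve", "data.frame")
  curve
}

#' Average precision of one precision-recall curve
#'
#' All-point interpolation: at each recall level the curve is replaced by
#' its precision envelope (the maximum precision attained at any recall at
#' least as large), and the area under that envelope is integrated exactly
#' over recall, starting from recall 0. This is the integral-over-recall
#' definition of AP; the older 11-point approximation is deliberately not
#' offered.
#'
#' @param curve A `pr_curve` (or data frame with `recall`/`precision`).
#' @return AP, a fraction in `[0, 1]`.
#' @export
average_precision <- function(curve) {
  r <- curve$recall
  p <- curve$precision
  if (!length(r)) return(0)
  if (is.unsorted(r))
    pt_validation_error("recall must be non-decreasing along the curve")
  env <- rev(cummax(rev(p)))
  sum(diff(c(0, r)) * env)
}

#' Mean average precision over classes
#'
#' @param curves A named list of per-class `pr_curve`s.
#' @param iou_threshold The IoU threshold the curves were computed at
#'   (metadata carried into the result).
#' @return An object of class `detection_metrics`: list with `ap` (named
#'   per-class vector), `map` (their arithmetic mean) and `iou_threshold`.
#' @export
average_precision_map <- function(curves, iou_threshold = 0.5) {
  if (!length(curves))
    pt_validation_error("need at least one class curve")
  ap <- vapply(curves, average_precision, numeric(1))
  structure(list(ap = ap, map = mean(ap), iou_threshold = iou_threshold),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> mAP@%g = %.4f\n", x$iou_threshold, x$map))
  for (cl in names(x$ap)) cat(sprintf("  AP[%s] = %.4f\n", cl, x$ap[[cl]]))
  invisible(x)
}

#' Evaluate a detection stream against ground truth
#'
#' Pooled per-class evaluation: matching is greedy and confidence-ordered
#' *within* each frame (a prediction can only hit a ground truth of the
#' same frame), the resulting flags are pooled over all frames and sorted
#' by score globally, and one PR curve / AP is computed per class. mAP is
#' the mean of the per-class APs.
#'
#' @param pred A [frame_stream()] of scored predictions.
#' @param gt A [frame_stream()] of ground-truth boxes (scores ignored).
#' @param iou_thresh IoU threshold for a true positive (default 0.5,
#'   i.e. mAP@0.5).
#' @param classes Classes to evaluate (default: all classes present in the
#'   ground truth).
#' @return A `detection_metrics` object.
#' @export
evaluate_detections <- function(pred, gt, iou_thresh = 0.5,
                                classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(gt$det$cls))
  if (!length(classes))
    pt_evaluation_error("no ground-truth classes to evaluate")
  curves <- lapply(classes, function(cl) {
    gt_cl <- stream_detections(gt, cls = cl)
    pr_cl <- stream_detections(pred, cls = cl)
    frames <- sort(unique(c(gt_cl$frame, pr_cl$frame)))
    flags <- lapply(frames, function(f) {
      g <- gt_cl[gt_cl$frame == f, , drop = FALSE]
      p <- pr_cl[pr_cl$frame == f, , drop = FALSE]
      match_detections(p$score, p, g, iou_thresh)
    })
    precision_recall(pool_match_flags(flags))
  })
  names(curves) <- classes
  average_precision_map(curves, iou_threshold = iou_thresh)
}
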