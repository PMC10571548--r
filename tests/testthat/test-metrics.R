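test_that("IoU worked examples", {
  b <- box(3, 4, 13, 24)
  expect_equal(box_iou(b, b), 1.0)
  expect_equal(box_iou(box(0, 0, 10, 10), box(10, 10, 20, 20)), 0.0)
  expect_equal(box_iou(box(0, 0, 2, 2), box(1, 1, 3, 3)), 1 / 7)
})

test_that("IoU is symmetric, bounded, and shift/scale invariant", {
  set.seed(42)
  for (k in 1:200) {
    a <- random_box(); b <- random_box()
    iou <- box_iou(a, b)
    expect_identical(iou, box_iou(b, a))
    expect_gte(iou, 0); expect_lte(iou, 1)
    dx <- runif(1, -50, 50); dy <- runif(1, -50, 50); s <- runif(1, 0.1, 5)
    shift <- function(z) box(z[["x1"]] + dx, z[["y1"]] + dy,
                             z[["x2"]] + dx, z[["y2"]] + dy)
    scale <- function(z) box(z[["x1"]] * s, z[["y1"]] * s,
                             z[["x2"]] * s, z[["y2"]] * s)
    expect_equal(box_iou(shift(a), shift(b)), iou, tolerance = 1e-12)
    expect_equal(box_iou(scale(a), scale(b)), iou, tolerance = 1e-12)
  }
})

test_that("greedy confidence-ordered matching follows the TP rule", {
  gt <- matrix(c(0, 0, 10, 10), 1)
  # both predictions overlap the single GT at IoU 2/3
  pred <- matrix(rep(c(0, 2, 10, 12), 2), 2, byrow = TRUE)
  fl <- match_detections(c(0.9, 0.8), pred, gt, iou_thresh = 0.5)
  expect_equal(fl$is_tp, c(TRUE, FALSE))
  expect_equal(fl$score, c(0.9, 0.8))
  expect_equal(fl$n_gt, 1L)

  # below-threshold overlap is a false positive
  low <- matrix(c(0, 5.2, 10, 15.2), 1)
  expect_lt(box_iou(box(0, 5.2, 10, 15.2), box(0, 0, 10, 10)), 0.5)
  fl <- match_detections(0.9, low, gt, 0.5)
  expect_false(fl$is_tp)

  # perfect detector: preds equal gts in any score order
  gts <- rbind(c(0, 0, 10, 10), c(50, 50, 70, 80), c(200, 0, 220, 30))
  fl <- match_detections(c(0.3, 0.9, 0.5), gts, gts, 0.5)
  expect_true(all(fl$is_tp))
  expect_equal(fl$n_gt - sum(fl$is_tp), 0L)  # FN = 0

  # degenerate sets
  fl <- match_detections(c(0.9), matrix(c(0, 0, 1, 1), 1),
                         matrix(numeric(0), 0, 4), 0.5)
  expect_equal(fl$is_tp, FALSE)
  fl <- match_detections(numeric(0), matrix(numeric(0), 0, 4), gts, 0.5)
  expect_length(fl$is_tp, 0L)
  expect_equal(fl$n_gt, 3L)
})

test_that("precision/recall arithmetic", {
  fl <- structure(list(score = seq(1, 0.1, length.out = 10),
                       is_tp = rep(c(TRUE, FALSE), c(8, 2)), n_gt = 10L),
                  class = "match_flags")
  pr <- precision_recall(fl)
  final <- pr[nrow(pr), ]
  expect_equal(final$recall, 0.8)     # TP/(TP+FN) = 8/10
  expect_equal(final$precision, 0.8)  # TP/(TP+FP) = 8/10

  fl <- structure(list(score = c(0.9, 0.8, 0.7),
                       is_tp = c(TRUE, FALSE, TRUE), n_gt = 3L),
                  class = "match_flags")
  pr <- precision_recall(fl)
  expect_equal(pr$recall, c(1/3, 1/3, 2/3))
  expect_equal(pr$precision, c(1, 1/2, 2/3))

  fl <- structure(list(score = c(0.9), is_tp = TRUE, n_gt = 1L),
                  class = "match_flags")
  pr <- precision_recall(fl)
  expect_equal(unlist(pr[1, ]), c(recall = 1, precision = 1))

  fl$n_gt <- 0L
  expect_error(precision_recall(fl), class = "pentrack_evaluation_error")
})

test_that("average precision uses the all-point precision envelope", {
  curve <- data.frame(recall = c(1/3, 1/3, 2/3), precision = c(1, 1/2, 2/3))
  expect_equal(average_precision(curve), 5 / 9)
  expect_equal(average_precision(data.frame(recall = 1, precision = 1)), 1)

  m <- average_precision_map(list(
    pig = data.frame(recall = 1, precision = 0.4),
    pig_fighting = data.frame(recall = 1, precision = 0.6)))
  expect_equal(unname(m$ap), c(0.4, 0.6))
  expect_equal(m$map, 0.5)
})

test_that("AP agrees with a brute-force envelope oracle", {
  set.seed(7)
  for (k in 1:25) {
    cur <- random_pr_curve(sample(2:25, 1))
    expect_equal(average_precision(cur), brute_force_ap(cur),
                 tolerance = 1e-9)
  }
  # mAP of identical per-class curves equals the single-class AP
  cur <- random_pr_curve(12)
  m <- average_precision_map(list(a = cur, b = cur, c = cur))
  expect_equal(m$map, average_precision(cur))
})

test_that("stream evaluation pools per-frame matches per class", {
  gt <- frame_stream(rbind(
    mk_det(1, 0, 0, 10, 10, 1, "pig"),
    mk_det(1, 50, 50, 80, 90, 1, "pig_fighting"),
    mk_det(2, 5, 5, 15, 15, 1, "pig")), fps = 25)
  res <- evaluate_detections(gt, gt, iou_thresh = 0.5)
  expect_equal(res$map, 1)
  expect_equal(unname(res$ap), c(1, 1))

  # a prediction cannot match a ground truth in another frame
  pred <- frame_stream(rbind(
    mk_det(2, 0, 0, 10, 10, 0.9, "pig"),       # right box, wrong frame
    mk_det(2, 5, 5, 15, 15, 0.8, "pig")), fps = 25)
  res <- evaluate_detections(pred, gt, iou_thresh = 0.5,
                             classes = "pig")
  expect_lt(res$map, 1)
})
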