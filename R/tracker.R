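# Two-stage (BYTE-style) data association over Kalman-predicted tracks.
#
# Per frame: detections are split at a score threshold; high-score
# detections are matched to all live (active or lost) tracks first, by
# Hungarian assignment on IoU distance; low-score detections are then
# offered to the still-unmatched *active* tracks — the occluded-animal
# rescue stage; leftover high-score detections above a stricter threshold
# found new tracks; tracks unmatched too long are removed. Lost tracks are
# retained for `max_lost_frames` frames (default 30) and can be re-matched
# when their animal reappears.

#' Tracker parameters
#'
#' @param high_thresh Score at or above which a detection counts as
#'   high-confidence (the BYTE split; default 0.6).
#' @param low_thresh Minimum usable score; detections below it are
#'   discarded entirely (default 0.1).
#' @param first_match_min_iou Minimum IoU for a first-stage match
#'   (default 0.2).
#' @param second_match_min_iou Minimum IoU for a second-stage (low-score)
#'   match; stricter, because low-score boxes are less trustworthy
#'   (default 0.5).
#' @param new_track_thresh Minimum score for an unmatched detection to
#'   found a new track (default 0.7).
#' @param max_lost_frames How many video frames an unmatched track is kept
#'   before removal (default 30).
#' @return An object of class `tracker_params`.
#' @export
tracker_params <- function(high_thresh = 0.6, low_thresh = 0.1,
                           first_match_min_iou = 0.2,
                           second_match_min_iou = 0.5,
                           new_track_thresh = 0.7,
                           max_lost_frames = 30L) {
  stopifnot_scalar_num(high_thresh, "high_thresh", 0, 1)
  stopifnot_scalar_num(low_thresh, "low_thresh", 0, 1)
  if (low_thresh >= high_thresh)
    pt_validation_error("need 0 <= low_thresh < high_thresh <= 1")
  stopifnot_scalar_num(first_match_min_iou, "first_match_min_iou", 0, 1)
  stopifnot_scalar_num(second_match_min_iou, "second_match_min_iou", 0, 1)
  stopifnot_scalar_num(new_track_thresh, "new_track_thresh", 0, 1)
  stopifnot_scalar_num(max_lost_frames, "max_lost_frames", lower = 1)
  structure(list(high_thresh = high_thresh, low_thresh = low_thresh,
                 first_match_min_iou = first_match_min_iou,
                 second_match_min_iou = second_match_min_iou,
                 new_track_thresh = new_track_thresh,
                 max_lost_frames = as.integer(max_lost_frames)),
            class = "tracker_params")
}

det_box <- function(d) box(d$x1, d$y1, d$x2, d$y2)

new_track <- function(id, det, cls, frame) {
  list(track_id = as.integer(id),
       state = kalman_initiate(det_box(det)),
       cls = cls,
       score = det$score,
       status = "active",
       frames_since_update = 0L,
       history = data.frame(frame = frame, x1 = det$x1, y1 = det$y1,
                            x2 = det$x2, y2 = det$y2, score = det$score))
}

track_hit <- function(tr, det, frame) {
  tr$state <- kalman_update(tr$state, det_box(det))
  b <- kalman_box(tr$state)
  tr$score <- det$score
  tr$status <- "active"
  tr$frames_since_update <- 0L
  tr$history <- rbind(tr$history,
                      data.frame(frame = frame, x1 = b[["x1"]],
                                 y1 = b[["y1"]], x2 = b[["x2"]],
                                 y2 = b[["y2"]], score = det$score))
  tr
}

track_miss <- function(tr, params) {
  tr$frames_since_update <- tr$frames_since_update + 1L
  tr$status <- if (tr$frames_since_update > params$max_lost_frames)
    "removed" else "lost"
  tr
}

track_boxes_matrix <- function(tracks) {
  if (!length(tracks)) return(matrix(numeric(0), 0L, 4L))
  do.call(rbind, lapply(tracks, function(tr) unclass(kalman_box(tr$state))))
}

# Deterministic within-frame ordering: by descending score, then box
# coordinates, so the result cannot depend on detector output order.
order_detections <- function(det) {
  det[order(-det$score, det$x1, det$y1, det$x2, det$y2), , drop = FALSE]
}

#' One frame of BYTE association
#'
#' Applies the two-stage association to one frame's detections. All tracks
#' must already be predicted to the current frame (see [kalman_predict()]).
#' Matched tracks are Kalman-corrected and their history extended;
#' unmatched detections above `new_track_thresh` found new tracks with
#' fresh, strictly increasing ids; unmatched tracks age and are removed
#' once `frames_since_update` exceeds `max_lost_frames`. Lost tracks take
#' part in the first (high-score) association only.
#'
#' @param tracks List of track objects (as produced by this function or
#'   [run_tracker()]'s loop).
#' @param detections Data frame of one frame's detections of one class
#'   (columns `x1, y1, x2, y2, score`).
#' @param params A [tracker_params()].
#' @param frame Current frame index (recorded into track histories).
#' @param next_id Next fresh track id.
#' @param cls Class of the stream being tracked.
#' @return A list with updated `tracks` and `next_id`.
#' @export
byte_associate_frame <- function(tracks, detections, params, frame,
                                 next_id = 1L, cls = "pig") {
  det <- order_detections(detections)
  det <- det[det$score >= params$low_thresh, , drop = FALSE]
  hi <- det[det$score >= params$high_thresh, , drop = FALSE]
  lo <- det[det$score < params$high_thresh, , drop = FALSE]

  live <- which(vapply(tracks, function(tr)
    tr$status %in% c("active", "lost"), logical(1)))

  # --- first association: high-score detections vs all live tracks
  cost1 <- 1 - iou_matrix(track_boxes_matrix(tracks[live]), hi)
  as1 <- linear_assignment(cost1, max_cost = 1 - params$first_match_min_iou)
  if (nrow(as1$matches)) {
    for (k in seq_len(nrow(as1$matches))) {
      ti <- live[as1$matches[k, 1L]]
      tracks[[ti]] <- track_hit(tracks[[ti]], hi[as1$matches[k, 2L], ], frame)
    }
  }

  # --- second association: low-score detections vs leftover *active* tracks
  left1 <- live[as1$unmatched_rows]
  pool2 <- left1[vapply(tracks[left1], function(tr)
    tr$status == "active", logical(1))]
  cost2 <- 1 - iou_matrix(track_boxes_matrix(tracks[pool2]), lo)
  as2 <- linear_assignment(cost2, max_cost = 1 - params$second_match_min_iou)
  if (nrow(as2$matches)) {
    for (k in seq_len(nrow(as2$matches))) {
      ti <- pool2[as2$matches[k, 1L]]
      tracks[[ti]] <- track_hit(tracks[[ti]], lo[as2$matches[k, 2L], ], frame)
    }
  }

  # --- births: unmatched high-score detections above the new-track bar
  for (j in as1$unmatched_cols) {
    if (hi$score[j] >= params$new_track_thresh) {
      tracks[[length(tracks) + 1L]] <- new_track(next_id, hi[j, ], cls, frame)
      next_id <- next_id + 1L
    }
  }

  # --- aging: every live track not matched this frame
  unmatched <- union(setdiff(left1, pool2), pool2[as2$unmatched_rows])
  for (ti in unmatched) tracks[[ti]] <- track_miss(tracks[[ti]], params)

  list(tracks = tracks, next_id = next_id)
}

#' Track one class of a detection stream
#'
#' The tracking-by-detection loop: for every video frame between the first
#' and the last frame of the stream (inclusive — frames with no detections
#' still age tracks), predict all live tracks one frame ahead, run the
#' two-stage association and Kalman-correct the matches. Track ids are
#' unique and never reused.
#'
#' @param stream A [frame_stream()].
#' @param params A [tracker_params()].
#' @param cls The class to track (`"pig"` or `"pig_fighting"`); each class
#'   is tracked as its own stream, a fight box is never a pig identity.
#' @return A list of [track_record()]s ordered by track id.
#' @export
run_tracker <- function(stream, params = tracker_params(), cls = "pig") {
  det <- stream_detections(stream, cls = cls)
  det <- det[det$score >= params$low_thresh, , drop = FALSE]
  if (!nrow(det)) return(list())
  tracks <- list()
  next_id <- 1L
  for (f in seq(min(det$frame), max(det$frame))) {
    for (i in seq_along(tracks)) {
      if (tracks[[i]]$status %in% c("active", "lost"))
        tracks[[i]]$state <- kalman_predict(tracks[[i]]$state)
    }
    step <- byte_associate_frame(tracks,
                                 det[det$frame == f, , drop = FALSE],
                                 params, frame = f, next_id = next_id,
                                 cls = cls)
    tracks <- step$tracks
    next_id <- step$next_id
  }
  tracks <- tracks[order(vapply(tracks, `[[`, integer(1), "track_id"))]
  lapply(tracks, function(tr) track_record(tr$track_id, tr$cls, tr$history))
}
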