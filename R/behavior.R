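# Phenotype extraction: per-identity movement statistics, fight-event
# intervals (the T1/T2 appear/disappear rule), fight participant
# attribution, and RFID ear-tag identity binding.

#' Movement distance, duration and speed of one track
#'
#' Draws the centroid polyline of a track (box centers joined frame to
#' frame) and accumulates the Euclidean distance between consecutive
#' centroids. Duration is `(last_frame - first_frame) / fps` seconds; mean
#' speed is distance over duration. With `px_per_m` given, distance and
#' speed are also reported in metres.
#'
#' @param track A [track_record()].
#' @param fps Frames per second (positive).
#' @param px_per_m Optional pixels-per-metre scale.
#' @return An object of class `movement_record`: `track_id`, `centroids`
#'   (data frame `frame, x, y`), `total_distance_px`, `duration_s`,
#'   `mean_speed_px_s`, optionally `total_distance_m` / `mean_speed_m_s`,
#'   and `degenerate` (TRUE for a single-box track, whose distance and
#'   speed are reported as 0).
#' @export
movement_statistics <- function(track, fps, px_per_m = NULL) {
  stopifnot_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  if (!is.null(px_per_m))
    stopifnot_scalar_num(px_per_m, "px_per_m", lower = 0, strict_lower = TRUE)
  b <- track$boxes
  if (!nrow(b)) pt_validation_error("track has no boxes")
  cx <- (b$x1 + b$x2) / 2
  cy <- (b$y1 + b$y2) / 2
  dist_px <- if (nrow(b) > 1L) sum(sqrt(diff(cx)^2 + diff(cy)^2)) else 0
  duration <- (max(b$frame) - min(b$frame)) / fps
  degenerate <- duration <= 0
  speed_px <- if (degenerate) 0 else dist_px / duration
  out <- list(track_id = track$track_id,
              centroids = data.frame(frame = b$frame, x = cx, y = cy),
              total_distance_px = dist_px,
              duration_s = duration,
              mean_speed_px_s = speed_px,
              degenerate = degenerate)
  if (!is.null(px_per_m)) {
    out$total_distance_m <- dist_px / px_per_m
    out$mean_speed_m_s <- speed_px / px_per_m
  }
  structure(out, class = "movement_record")
}

#' @export
print.movement_record <- function(x, ...) {
  cat(sprintf("<movement_record> id %d: %.1f px over %.2f s (%.2f px/s)\n",
              x$track_id, x$total_distance_px, x$duration_s,
              x$mean_speed_px_s))
  invisible(x)
}

new_fight_event <- function(frames, boxes, fps, participants = integer(0)) {
  t1 <- min(frames); t2 <- max(frames)
  structure(list(t1_frame = t1, t2_frame = t2,
                 t1_s = t1 / fps, t2_s = t2 / fps,
                 n_frames = t2 - t1 + 1L,
                 boxes = boxes,
                 participants = participants),
            class = "fight_event")
}

#' @export
print.fight_event <- function(x, ...) {
  cat(sprintf("<fight_event> frames [%d, %d] (%.2f-%.2f s)%s\n",
              x$t1_frame, x$t2_frame, x$t1_s, x$t2_s,
              if (length(x$participants))
                paste0(", pigs {", paste(x$participants, collapse = ","), "}")
              else ""))
  invisible(x)
}

# Union-find for clustering fight detections.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Extract fight events from the aggression-class detections
#'
#' The timing rule: the moment a fight detection box appears is T1, the
#' moment it disappears is T2. Operationally, maximal runs of frames
#' containing at least one `pig_fighting` detection become events; runs
#' separated by at most `merge_gap_frames` empty frames are merged (this
#' debounces single-frame detector flicker), and merged runs shorter than
#' `min_len_frames` are dropped. Both endpoints are reported in frames and
#' in seconds via the stream's fps.
#'
#' Two spatially distinct simultaneous fights are split into separate
#' events: fight detections are first clustered by spatio-temporal
#' connectivity (boxes within `merge_gap_frames + 1` frames of each other
#' that overlap belong to one fight); clusters that do not overlap in time
#' are then merged by the pure temporal rule above.
#'
#' @param stream A [frame_stream()]; only its `pig_fighting` detections
#'   are used.
#' @param min_len_frames Minimum event length in frames (default 3).
#' @param merge_gap_frames Maximum run separation, in empty frames, that
#'   is still bridged (default 12).
#' @return A list of `fight_event` objects, ordered by T1.
#' @export
fight_intervals <- function(stream, min_len_frames = 3L,
                            merge_gap_frames = 12L) {
  stopifnot_scalar_num(min_len_frames, "min_len_frames", lower = 1)
  stopifnot_scalar_num(merge_gap_frames, "merge_gap_frames", lower = 0)
  det <- stream_detections(stream, cls = "pig_fighting")
  if (!nrow(det)) return(list())
  det <- det[order(det$frame), , drop = FALSE]
  n <- nrow(det)

  # spatio-temporal clustering (union-find)
  parent <- seq_len(n)
  window <- merge_gap_frames + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      dt <- det$frame[j] - det$frame[i]
      if (dt > window) break
      if (box_iou(c(x1 = det$x1[i], y1 = det$y1[i],
                    x2 = det$x2[i], y2 = det$y2[i]),
                  c(x1 = det$x1[j], y1 = det$y1[j],
                    x2 = det$x2[j], y2 = det$y2[j])) > 0) {
        ri <- uf_find(parent, i); rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comps <- split(seq_len(n), roots)

  # one run per cluster, then the temporal merge rule across
  # non-overlapping runs
  runs <- lapply(comps, function(idx) {
    list(t1 = min(det$frame[idx]), t2 = max(det$frame[idx]), idx = idx)
  })
  runs <- runs[order(vapply(runs, `[[`, numeric(1), "t1"),
                     vapply(runs, `[[`, numeric(1), "t2"))]
  merged <- list()
  for (r in runs) {
    if (length(merged)) {
      last <- merged[[length(merged)]]
      gap <- r$t1 - last$t2 - 1L
      if (r$t1 > last$t2 && gap <= merge_gap_frames) {
        last$t2 <- max(last$t2, r$t2)
        last$idx <- c(last$idx, r$idx)
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }

  events <- lapply(merged, function(r) {
    if (r$t2 - r$t1 + 1L < min_len_frames) return(NULL)
    rows <- det[sort(r$idx), , drop = FALSE]
    # one representative box per frame: the union of the cluster's boxes
    boxes <- do.call(rbind, lapply(split(rows, rows$frame), function(g) {
      data.frame(frame = g$frame[1L], x1 = min(g$x1), y1 = min(g$y1),
                 x2 = max(g$x2), y2 = max(g$y2))
    }))
    rownames(boxes) <- NULL
    new_fight_event(rows$frame, boxes, stream$fps)
  })
  Filter(Negate(is.null), events)
}

#' Attribute a fight event to the pigs involved
#'
#' Ranks pig tracks by their mean IoU with the event's fight box over the
#' event's frames (frames where a track has no box contribute 0) and
#' returns the top two with strictly positive mean IoU — a fight involves
#' at most two animals. Fewer than two qualifying tracks yield a smaller
#' set; none yield an empty set with a warning.
#'
#' @param event A `fight_event` (from [fight_intervals()]).
#' @param pig_tracks A list of [track_record()]s of class `"pig"`.
#' @param fight_boxes Optional data frame `frame, x1, y1, x2, y2` of the
#'   fight box per frame; defaults to the boxes stored in the event.
#' @return Integer vector of at most two track ids.
#' @export
fight_participants <- function(event, pig_tracks,
                               fight_boxes = event$boxes) {
  if (is.null(fight_boxes) || !nrow(fight_boxes))
    pt_validation_error("event has no fight boxes")
  mean_iou <- vapply(pig_tracks, function(tr) {
    b <- tr$boxes
    ious <- vapply(seq_len(nrow(fight_boxes)), function(k) {
      row <- b[b$frame == fight_boxes$frame[k], , drop = FALSE]
      if (!nrow(row)) return(0)
      box_iou(c(x1 = row$x1, y1 = row$y1, x2 = row$x2, y2 = row$y2),
              c(x1 = fight_boxes$x1[k], y1 = fight_boxes$y1[k],
                x2 = fight_boxes$x2[k], y2 = fight_boxes$y2[k]))
    }, numeric(1))
    mean(ious)
  }, numeric(1))
  ids <- vapply(pig_tracks, `[[`, integer(1), "track_id")
  ord <- order(-mean_iou, ids)
  qual <- ord[mean_iou[ord] > 0]
  if (!length(qual)) {
    warning("no pig track overlaps the fight box; participants unknown")
    return(integer(0))
  }
  sort(ids[utils::head(qual, 2L)])
}

#' RFID ear-tag identity binding
#'
#' At each ear-tag read, the unique track whose centroid lies inside the
#' feeder zone within `tol_s` seconds of the read timestamp is bound to
#' the tag. A later read that binds a tag already held by a track that has
#' since ended transfers the tag to the new track — the re-identification
#' path after target loss. Reads with no candidate track, with several
#' candidate tracks (ambiguous), or whose candidate already holds a
#' different tag are skipped and logged. A read that would bind one tag to
#' two simultaneously live tracks raises an error.
#'
#' @param tracks List of [track_record()]s.
#' @param reads Data frame with columns `timestamp` (seconds,
#'   non-negative) and `tag_id` (character).
#' @param zone A [box()]: the feeder-station region.
#' @param fps Frames per second (converts timestamps to frames).
#' @param tol_s Read-to-track tolerance window in seconds (default 0.5).
#' @return An object of class `identity_map`: list with `map` (named
#'   character vector, track id -> tag id), `zone` and `log` (one row per
#'   read with its outcome).
#' @export
rfid_link <- function(tracks, reads, zone, fps, tol_s = 0.5) {
  stopifnot_scalar_num(fps, "fps", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_num(tol_s, "tol_s", lower = 0)
  if (!is.data.frame(reads) || !all(c("timestamp", "tag_id") %in% names(reads)))
    pt_validation_error("reads need columns timestamp, tag_id")
  if (nrow(reads) && any(reads$timestamp < 0))
    pt_validation_error("RFID timestamps must be non-negative")
  reads <- reads[order(reads$timestamp), , drop = FALSE]
  ids <- vapply(tracks, `[[`, integer(1), "track_id")
  last_frame <- vapply(tracks, function(tr) max(tr$boxes$frame), numeric(1))
  map <- character(0)
  log <- list()
  in_zone_at <- function(tr, f_lo, f_hi) {
    b <- tr$boxes[tr$boxes$frame >= f_lo & tr$boxes$frame <= f_hi, ,
                  drop = FALSE]
    if (!nrow(b)) return(FALSE)
    cx <- (b$x1 + b$x2) / 2
    cy <- (b$y1 + b$y2) / 2
    any(cx >= zone[["x1"]] & cx <= zone[["x2"]] &
        cy >= zone[["y1"]] & cy <= zone[["y2"]])
  }
  for (k in seq_len(nrow(reads))) {
    t <- reads$timestamp[k]
    tag <- as.character(reads$tag_id[k])
    f_lo <- ceiling((t - tol_s) * fps)
    f_hi <- floor((t + tol_s) * fps)
    cand <- which(vapply(tracks, in_zone_at, logical(1), f_lo, f_hi))
    outcome <- NA_character_; bound <- NA_integer_
    if (!length(cand)) {
      outcome <- "no_track"
    } else if (length(cand) > 1L) {
      outcome <- "ambiguous"
    } else {
      ti <- cand
      id <- ids[ti]
      holder <- names(map)[map == tag]
      if (length(holder) && holder == as.character(id)) {
        outcome <- "confirmed"; bound <- id
      } else if (length(holder)) {
        hi <- which(ids == as.integer(holder))
        holder_live <- last_frame[hi] >= f_lo
        if (holder_live)
          pt_validation_error(sprintf(
            "tag %s read for track %d while still live on track %s",
            tag, id, holder))
        map <- map[names(map) != holder]
        map[as.character(id)] <- tag
        outcome <- "transferred"; bound <- id
      } else if (as.character(id) %in% names(map)) {
        outcome <- "conflict"   # track already carries another tag
      } else {
        map[as.character(id)] <- tag
        outcome <- "bound"; bound <- id
      }
    }
    log[[k]] <- data.frame(timestamp = t, tag_id = tag, outcome = outcome,
                           track_id = bound, stringsAsFactors = FALSE)
  }
  structure(list(map = map, zone = zone,
                 log = if (length(log)) do.call(rbind, log) else
                   data.frame(timestamp = numeric(0), tag_id = character(0),
                              outcome = character(0),
                              track_id = integer(0))),
            class = "identity_map")
}
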