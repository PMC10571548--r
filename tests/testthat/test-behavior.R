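centroid_track <- function(id, frames, cx, cy, w = 10, h = 10) {
  track_record(id, "pig", data.frame(
    frame = frames, x1 = cx - w / 2, y1 = cy - h / 2,
    x2 = cx + w / 2, y2 = cy + h / 2, score = 0.9))
}

test_that("movement distance accumulates consecutive centroid segments", {
  tr <- centroid_track(1L, 1:3, c(0, 3, 6), c(0, 4, 8))
  mv <- movement_statistics(tr, fps = 25)
  expect_equal(mv$total_distance_px, 10)  # two 3-4-5 segments

  # unit conversion: 10 px over 2 frames at 2 fps, 100 px/m
  tr <- centroid_track(2L, c(1, 3), c(0, 6), c(0, 8))
  mv <- movement_statistics(tr, fps = 2, px_per_m = 100)
  expect_equal(mv$total_distance_m, 0.1)
  expect_equal(mv$duration_s, 1.0)
  expect_equal(mv$mean_speed_m_s, 0.1)
  expect_equal(mv$mean_speed_px_s, mv$total_distance_px / mv$duration_s)

  # stationary and single-box degenerate cases
  mv <- movement_statistics(centroid_track(3L, 1:50, rep(7, 50), rep(9, 50)),
                            fps = 25)
  expect_equal(mv$total_distance_px, 0)
  mv <- movement_statistics(centroid_track(4L, 5, 1, 1), fps = 25)
  expect_true(mv$degenerate)
  expect_equal(mv$mean_speed_px_s, 0)
})

test_that("movement distance is invariant to rigid motion, scales linearly", {
  set.seed(12)
  frames <- 1:40
  cx <- cumsum(rnorm(40)); cy <- cumsum(rnorm(40))
  base <- movement_statistics(centroid_track(1L, frames, cx, cy), 25)
  shifted <- movement_statistics(
    centroid_track(1L, frames, cx + 100, cy - 40), 25)
  th <- 0.7
  rot <- movement_statistics(centroid_track(
    1L, frames, cos(th) * cx - sin(th) * cy, sin(th) * cx + cos(th) * cy), 25)
  scaled <- movement_statistics(centroid_track(1L, frames, 3 * cx, 3 * cy), 25)
  expect_equal(shifted$total_distance_px, base$total_distance_px)
  expect_equal(rot$total_distance_px, base$total_distance_px)
  expect_equal(scaled$total_distance_px, 3 * base$total_distance_px)
  # polyline length >= straight-line displacement
  straight <- sqrt((cx[40] - cx[1])^2 + (cy[40] - cy[1])^2)
  expect_gte(base$total_distance_px, straight)
})

fight_stream <- function(frames, x1 = 0, y1 = 0, x2 = 50, y2 = 40,
                         fps = 25) {
  frame_stream(stationary_det(frames, x1, y1, x2, y2, 0.9, "pig_fighting"),
               fps)
}

test_that("fight intervals follow the appear/disappear (T1/T2) rule", {
  ev <- fight_intervals(fight_stream(5:9), min_len_frames = 1,
                        merge_gap_frames = 0)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$t1_frame, 5L)
  expect_equal(ev[[1]]$t2_frame, 9L)
  expect_equal(ev[[1]]$t1_s, 5 / 25)
  expect_equal(ev[[1]]$n_frames, 5L)

  # merge rule: runs 10-20 and 22-30
  s <- fight_stream(c(10:20, 22:30))
  expect_length(fight_intervals(s, 1, merge_gap_frames = 2), 1L)
  ev <- fight_intervals(s, 1, merge_gap_frames = 2)
  expect_equal(c(ev[[1]]$t1_frame, ev[[1]]$t2_frame), c(10L, 30L))
  expect_length(fight_intervals(s, 1, merge_gap_frames = 0), 2L)

  # min length filter
  expect_length(fight_intervals(fight_stream(4:5), min_len_frames = 3,
                                merge_gap_frames = 0), 0L)
  expect_length(fight_intervals(frame_stream(fps = 25)), 0L)
})

test_that("interval extraction partitions fight frames and is monotone", {
  set.seed(31)
  frames <- sort(sample(1:200, 60))
  s <- fight_stream(frames)
  ev <- fight_intervals(s, min_len_frames = 1, merge_gap_frames = 0)
  covered <- unlist(lapply(ev, function(e) e$boxes$frame))
  expect_setequal(covered, frames)
  # maximal runs: consecutive events separated by >= 1 empty frame
  t1 <- vapply(ev, `[[`, integer(1), "t1_frame")
  t2 <- vapply(ev, `[[`, integer(1), "t2_frame")
  expect_true(all(t1[-1] > t2[-length(t2)] + 1L))
  # increasing merge_gap never increases the event count
  counts <- vapply(c(0, 1, 2, 5, 10, 25), function(g)
    length(fight_intervals(s, 1, g)), integer(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("simultaneous spatially distinct fights become separate events", {
  two <- rbind(stationary_det(10:20, 0, 0, 50, 40, 0.9, "pig_fighting"),
               stationary_det(10:20, 500, 500, 560, 540, 0.9, "pig_fighting"))
  ev <- fight_intervals(frame_stream(two, 25), 1, 0)
  expect_length(ev, 2L)
  expect_true(all(vapply(ev, `[[`, integer(1), "t1_frame") == 10L))
})

test_that("participants are the two tracks with highest mean IoU", {
  tracks <- list(
    centroid_track(1L, 1:20, rep(50, 20), rep(50, 20), w = 60, h = 40),
    centroid_track(2L, 1:20, rep(100, 20), rep(50, 20), w = 60, h = 40),
    centroid_track(3L, 1:20, rep(800, 20), rep(600, 20), w = 60, h = 40))
  # fight box = union of pigs 1 and 2
  fights <- frame_stream(stationary_det(5:15, 20, 30, 130, 70,
                                        0.9, "pig_fighting"), 25)
  ev <- fight_intervals(fights, 1, 0)[[1]]
  expect_equal(fight_participants(ev, tracks), c(1L, 2L))

  # nobody overlaps: empty set with a warning
  far <- frame_stream(stationary_det(5:15, 2000, 2000, 2100, 2100,
                                     0.9, "pig_fighting"), 25)
  ev_far <- fight_intervals(far, 1, 0)[[1]]
  expect_warning(p <- fight_participants(ev_far, tracks))
  expect_length(p, 0L)

  # a single qualifying track yields a singleton
  expect_equal(fight_participants(ev, tracks[c(1, 3)]), 1L)
})

test_that("RFID binding, ambiguity and tag transfer after target loss", {
  zone <- box(0, 0, 200, 200)
  fps <- 10
  t1 <- centroid_track(1L, 1:500, rep(100, 500), rep(100, 500))   # in zone
  t2 <- centroid_track(2L, 1:500, rep(900, 500), rep(900, 500))   # outside
  t3 <- centroid_track(3L, 600:1000, rep(100, 401), rep(100, 401))

  reads <- data.frame(timestamp = 10, tag_id = "TAG07")
  m <- rfid_link(list(t1, t2), reads, zone, fps)
  expect_equal(m$map, c(`1` = "TAG07"))
  expect_equal(m$log$outcome, "bound")

  # track 1 ends at frame 500; tag read again at t=90 s (frame 900) while
  # track 3 is in the zone -> transfer, histories concatenable under one tag
  reads2 <- data.frame(timestamp = c(10, 90), tag_id = "TAG07")
  m <- rfid_link(list(t1, t2, t3), reads2, zone, fps)
  expect_equal(m$map, c(`3` = "TAG07"))
  expect_equal(m$log$outcome, c("bound", "transferred"))

  # two centroids in the zone at the read: ambiguous, skipped and logged
  t2b <- centroid_track(2L, 1:500, rep(120, 500), rep(120, 500))
  m <- rfid_link(list(t1, t2b), reads, zone, fps)
  expect_length(m$map, 0L)
  expect_equal(m$log$outcome, "ambiguous")

  # no track in zone: logged, no binding
  m <- rfid_link(list(t2), reads, zone, fps)
  expect_equal(m$log$outcome, "no_track")

  # binding one tag to two live tracks is an invariant violation: the
  # holder leaves the zone but stays live while another track reads the tag
  reads3 <- data.frame(timestamp = c(10, 20), tag_id = "TAG07")
  t1_moving <- centroid_track(1L, 1:500,
                              c(rep(100, 150), rep(900, 350)),
                              rep(100, 500))
  t2c <- centroid_track(2L, 150:500, rep(100, 351), rep(100, 351))
  expect_error(rfid_link(list(t1_moving, t2c), reads3, zone, fps),
               class = "pentrack_validation_error")
})
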