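test_that("reader converts MOT rows to corner boxes and groups frames", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("1,-1,10,20,30,40,0.9,0,1",
               "2,-1,50,60,10,10,0.8,1,1",
               "1,-1,100,100,20,20,0.7,0,1"), f)
  s <- read_mot_detections(f, fps = 25)
  expect_s3_class(s, "frame_stream")
  expect_equal(nrow(s$det), 3L)  # reader never invents frames
  d1 <- s$det[s$det$frame == 1L, ]
  expect_equal(nrow(d1), 2L)
  expect_equal(unname(unlist(d1[1, c("x1", "y1", "x2", "y2")])),
               c(10, 20, 40, 60))
  expect_equal(d1$cls[1], "pig")
  expect_equal(s$det$cls[s$det$frame == 2L], "pig_fighting")
  expect_equal(s$fps, 25)
})

test_that("reader rejects malformed input with line numbers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("1,-1,10,20,30,40,0.9,0,1",
               "2,-1,10,20,0,40,0.9,0,1"), f)
  expect_error(read_mot_detections(f, 25), "line 2",
               class = "pentrack_parse_error")

  writeLines(c("1,-1,10,20,30,40,0.9,0"), f)  # 8 fields
  expect_error(read_mot_detections(f, 25), "line 1",
               class = "pentrack_parse_error")

  writeLines(c("1,-1,10,20,30,40,0.9,7,1"), f)  # unknown class code
  expect_error(read_mot_detections(f, 25), "class",
               class = "pentrack_validation_error")

  writeLines(c("1,-1,ten,20,30,40,0.9,0,1"), f)
  expect_error(read_mot_detections(f, 25), "line 1",
               class = "pentrack_parse_error")

  expect_error(read_mot_detections(tempfile(), 25),
               class = "pentrack_missing_input")
})

test_that("empty file yields an empty stream, not an error", {
  f <- tempfile(fileext = ".csv")
  writeLines(character(0), f)
  s <- read_mot_detections(f, fps = 10)
  expect_equal(nrow(s$det), 0L)
})

test_that("track writer round-trips through the reader at 2 decimals", {
  set.seed(101)
  tracks <- lapply(1:5, function(id) {
    frames <- sort(sample(1:40, 12))
    boxes <- do.call(rbind, lapply(frames, function(f) {
      b <- random_box(500)
      data.frame(frame = f, x1 = b[["x1"]], y1 = b[["y1"]],
                 x2 = b[["x2"]], y2 = b[["y2"]],
                 score = round(runif(1), 2))
    }))
    track_record(id, if (id == 5) "pig_fighting" else "pig", boxes)
  })
  f <- tempfile(fileext = ".csv")
  write_mot_tracks(tracks, f)
  back <- read_mot_tracks(f)
  expect_length(back, 5L)
  for (k in 1:5) {
    expect_equal(back[[k]]$track_id, tracks[[k]]$track_id)
    expect_equal(back[[k]]$cls, tracks[[k]]$cls)
    expect_equal(back[[k]]$boxes$frame, tracks[[k]]$boxes$frame)
    expect_equal(as.matrix(back[[k]]$boxes[, c("x1", "y1", "x2", "y2")]),
                 as.matrix(tracks[[k]]$boxes[, c("x1", "y1", "x2", "y2")]),
                 tolerance = 1e-2, ignore_attr = TRUE)
    expect_equal(back[[k]]$boxes$score, tracks[[k]]$boxes$score,
                 tolerance = 1e-2)
  }
})

test_that("track writer validates and handles the empty case", {
  t1 <- track_record(1L, "pig", data.frame(
    frame = c(1, 2), x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.5))
  f <- tempfile(fileext = ".csv")
  write_mot_tracks(list(t1), f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_true(all(grepl("^[12],1,", lines)))  # same id column

  # duplicate (frame, id) across records
  expect_error(write_mot_tracks(list(t1, t1), f),
               class = "pentrack_validation_error")

  write_mot_tracks(list(), f)
  expect_length(readLines(f), 0L)
  expect_length(read_mot_tracks(f), 0L)
})

test_that("domain type invariants are enforced", {
  expect_error(box(0, 0, 0, 10), class = "pentrack_validation_error")
  expect_error(track_record(0L, "pig", data.frame(
    frame = 1, x1 = 0, y1 = 0, x2 = 1, y2 = 1, score = 1)),
    class = "pentrack_validation_error")
  expect_error(track_record(1L, "pig", data.frame(
    frame = c(3, 3), x1 = 0, y1 = 0, x2 = 1, y2 = 1, score = 1)),
    class = "pentrack_validation_error")
  expect_error(frame_stream(mk_det(1, 0, 0, 10, 10, score = 1.2), 25),
               class = "pentrack_validation_error")
  expect_error(frame_stream(mk_det(1, 0, 0, 10, 10), fps = 0),
               class = "pentrack_validation_error")
})
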