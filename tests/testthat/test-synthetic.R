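test_that("the simulator is deterministic under a fixed seed", {
  cfg <- scenario_config(n_pigs = 8L, n_frames = 100L, seed = 42L,
    fight_episodes = list(list(start = 30L, end = 60L, pair = c(1L, 2L))))
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$stream$det, b$stream$det)
  expect_identical(a$truth$distances, b$truth$distances)
  c_ <- simulate_scenario(scenario_config(n_pigs = 8L, n_frames = 100L,
                                          seed = 43L))
  expect_false(identical(a$stream$det$x1, c_$stream$det$x1))
})

test_that("the noiseless limit emits exactly the true boxes", {
  cfg <- noiseless_config(n_pigs = 5L, n_frames = 60L, layout = "grid",
                          seed = 2L)
  sim <- simulate_scenario(cfg)
  det <- sim$stream$det
  expect_equal(nrow(det), 5L * 60L)  # no misses
  for (f in c(1L, 30L, 60L)) {
    d <- det[det$frame == f, ]
    truth <- do.call(rbind, lapply(sim$truth$tracks, function(tr)
      tr$boxes[tr$boxes$frame == f, c("x1", "y1", "x2", "y2")]))
    expect_equal(sort(d$x1), sort(truth$x1), tolerance = 1e-12)
    expect_equal(sort(d$y2), sort(truth$y2), tolerance = 1e-12)
  }
})

test_that("scripted fight episodes appear in truth and in the stream", {
  cfg <- noiseless_config(n_pigs = 6L, n_frames = 200L, seed = 5L,
    fight_episodes = list(list(start = 100L, end = 180L, pair = c(2L, 5L))))
  sim <- simulate_scenario(cfg)
  expect_length(sim$truth$fights, 1L)
  ev <- sim$truth$fights[[1]]
  expect_equal(c(ev$t1_frame, ev$t2_frame), c(100L, 180L))
  expect_equal(ev$participants, c(2L, 5L))
  fight_det <- stream_detections(sim$stream, cls = "pig_fighting")
  expect_setequal(unique(fight_det$frame), 100:180)
  # the fight box encloses both participants (union box)
  f <- 140L
  fd <- fight_det[fight_det$frame == f, ]
  for (i in c(2L, 5L)) {
    tb <- sim$truth$tracks[[i]]$boxes
    tb <- tb[tb$frame == f, ]
    expect_lte(fd$x1, tb$x1); expect_gte(fd$x2, tb$x2)
    expect_lte(fd$y1, tb$y1); expect_gte(fd$y2, tb$y2)
  }
  # participants' boxes overlap during the fight
  b2 <- sim$truth$tracks[[2L]]$boxes; b2 <- b2[b2$frame == f, ]
  b5 <- sim$truth$tracks[[5L]]$boxes; b5 <- b5[b5$frame == f, ]
  expect_gt(box_iou(box(b2$x1, b2$y1, b2$x2, b2$y2),
                    box(b5$x1, b5$y1, b5$x2, b5$y2)), 0)
})

test_that("generator distance bookkeeping matches movement_statistics", {
  cfg <- scenario_config(n_pigs = 7L, n_frames = 150L, seed = 9L)
  sim <- simulate_scenario(cfg)
  for (i in seq_len(cfg$n_pigs)) {
    mv <- movement_statistics(sim$truth$tracks[[i]], cfg$fps)
    expect_equal(mv$total_distance_px, unname(sim$truth$distances[i]),
                 tolerance = 1e-6)
  }
})

test_that("true boxes never leave the pen; infeasible configs error", {
  cfg <- scenario_config(n_pigs = 15L, n_frames = 80L, seed = 23L)
  sim <- simulate_scenario(cfg)
  pen <- cfg$pen
  for (tr in sim$truth$tracks) {
    expect_true(all(tr$boxes$x1 >= pen[["x1"]] - 1e-9))
    expect_true(all(tr$boxes$y1 >= pen[["y1"]] - 1e-9))
    expect_true(all(tr$boxes$x2 <= pen[["x2"]] + 1e-9))
    expect_true(all(tr$boxes$y2 <= pen[["y2"]] + 1e-9))
  }
  expect_error(scenario_config(pen = box(0, 0, 200, 100)),
               class = "pentrack_validation_error")
  expect_error(scenario_config(fight_episodes = list(
    list(start = 1L, end = 999L, pair = c(1L, 2L)))),
    class = "pentrack_validation_error")
})

test_that("tracking evaluation scores perfect and swapped predictions", {
  cfg <- noiseless_config(n_pigs = 4L, n_frames = 50L, layout = "grid",
                          seed = 8L)
  sim <- simulate_scenario(cfg)
  # pred == truth
  ev <- evaluate_tracking(sim$truth$tracks, sim$truth)
  expect_equal(ev$id_switches, 0L)
  expect_equal(ev$fragmentation, 0L)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$frame_agreement, 1.0)

  # swap two predicted ids mid-sequence: one switch per affected truth track
  swap_at <- 25L
  pred <- sim$truth$tracks
  b1 <- pred[[1]]$boxes; b2 <- pred[[2]]$boxes
  pred[[1]] <- track_record(1L, "pig",
    rbind(b1[b1$frame < swap_at, ], b2[b2$frame >= swap_at, ]))
  pred[[2]] <- track_record(2L, "pig",
    rbind(b2[b2$frame < swap_at, ], b1[b1$frame >= swap_at, ]))
  ev <- evaluate_tracking(pred, sim$truth)
  expect_equal(ev$id_switches, 2L)
  expect_equal(ev$fragmentation, 2L)
  expect_equal(ev$recall, 1.0)

  # empty predictions
  ev <- evaluate_tracking(list(), sim$truth)
  expect_equal(ev$recall, 0)
  expect_equal(ev$id_switches, 0L)
})

test_that("deleting every second frame does not fragment identities", {
  cfg <- noiseless_config(n_pigs = 5L, n_frames = 120L, layout = "grid",
                          seed = 13L)
  sim <- simulate_scenario(cfg)
  det <- sim$stream$det
  thinned <- frame_stream(det[det$frame %% 2L == 1L, ], cfg$fps)
  recs <- run_tracker(thinned)
  ev <- evaluate_tracking(recs, sim$truth)
  expect_equal(ev$fragmentation, 0L)  # same id bridges every gap
  expect_equal(ev$id_switches, 0L)
  expect_length(recs, 5L)
})
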