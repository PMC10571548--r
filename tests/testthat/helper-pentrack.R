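# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration, O(n^2) scans) and never share code with the
# implementation paths they check.

mk_det <- function(frame, x1, y1, x2, y2, score = 0.9, cls = "pig") {
  data.frame(frame = frame, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
             score = score, cls = cls, stringsAsFactors = FALSE)
}

# A stationary pig: identical box over the given frames.
stationary_det <- function(frames, x1, y1, x2, y2, score = 0.9,
                           cls = "pig") {
  do.call(rbind, lapply(frames, mk_det, x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                        score = score, cls = cls))
}

random_box <- function(lim = 100) {
  x1 <- runif(1, 0, lim); y1 <- runif(1, 0, lim)
  box(x1, y1, x1 + runif(1, 1, lim / 2), y1 + runif(1, 1, lim / 2))
}

# Exhaustive minimum assignment cost over all injective row -> column maps.
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) return(brute_force_assignment_cost(t(cost)))
  best <- Inf
  recurse <- function(row, used, acc) {
    if (row > n) {
      best <<- min(best, acc)
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(row + 1L, used, acc + cost[row, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(m), 0)
  best
}

# All-point-interpolated AP by brute force: for each recall segment take
# the max precision over every point at recall >= the segment's right
# endpoint, scanning the whole curve each time.
brute_force_ap <- function(curve) {
  r <- curve$recall; p <- curve$precision
  if (!length(r)) return(0)
  total <- 0
  prev <- 0
  for (k in seq_along(r)) {
    env <- max(p[r >= r[k]])
    total <- total + (r[k] - prev) * env
    prev <- r[k]
  }
  total
}

random_pr_curve <- function(n = 10L) {
  r <- sort(runif(n))
  data.frame(recall = r, precision = runif(n))
}

# Two stationary pigs far apart plus helpers used by behavior tests.
two_track_fixture <- function(frames = 1:10) {
  list(
    a = track_record(1L, "pig", data.frame(
      frame = frames, x1 = 0, y1 = 0, x2 = 100, y2 = 50, score = 0.9)),
    b = track_record(2L, "pig", data.frame(
      frame = frames, x1 = 500, y1 = 500, x2 = 600, y2 = 550, score = 0.9))
  )
}

noiseless_config <- function(...) {
  # the stated noiseless world: perfect boxes, no misses, and a confident
  # detector (scores concentrated near 0.9)
  scenario_config(jitter_sd = 0, miss_prob = 0, occ_miss_boost = 0,
                  score_high = c(60, 8), ...)
}
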