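seq_of <- function(labels, stride = 10L, window_len = 180L, fs = 200) {
  label_sequence(labels, make_windowset(length(labels), window_len, stride, fs))
}

test_that("predict_sequence reflects the committee on clean sessions", {
  com <- full_committee_fixture("binary")
  # all-background stream: all-zero sequence
  bg <- generate_session(synthetic_config(duration_s = 8, n_punches = 0, seed = 42))
  w <- make_windows(bg$stream, 180, 10)
  f <- extract_features(bg$stream, w)
  s <- predict_sequence(com, f, w)
  expect_true(all(s$labels == 0L))

  # one centered punch: a contiguous 1-run covering it
  one <- generate_session(synthetic_config(duration_s = 8, n_punches = 1, seed = 43))
  w1 <- make_windows(one$stream, 180, 10)
  f1 <- extract_features(one$stream, w1)
  s1 <- smooth_labels(predict_sequence(com, f1, w1))
  ev <- extract_events(s1)
  expect_equal(nrow(ev), 1L)
  mid <- (ev$start_s + ev$end_s) / 2
  expect_gte(mid, one$events$start_s)
  expect_lte(mid, one$events$end_s)

  # feature-column mismatch is an error
  expect_error(predict_sequence(com, f1[, 1:30], w1), "feature columns")
})

test_that("smoothing fills short gaps then drops short runs, in that order", {
  # 0.15 s gap (3 windows at stride 10 @ 200 Hz) between two solid runs: merged
  lab <- c(rep(0, 5), rep(1, 8), rep(0, 3), rep(1, 8), rep(0, 5))
  sm <- smooth_labels(seq_of(lab))
  expect_equal(nrow(extract_events(sm)), 1L)

  # isolated 0.1 s run (2 windows): removed
  lab2 <- c(rep(0, 5), rep(1, 2), rep(0, 5))
  sm2 <- smooth_labels(seq_of(lab2))
  expect_true(all(sm2$labels == 0L))

  # clean alternation with all runs >= 0.2 s: a fixed point
  lab3 <- c(rep(0, 6), rep(1, 6), rep(0, 6), rep(1, 6), rep(0, 6))
  sm3 <- smooth_labels(seq_of(lab3))
  expect_identical(sm3$labels, as.integer(lab3))

  # leading/trailing zeros are never flipped, even when short
  lab4 <- c(0, rep(1, 8), 0)
  sm4 <- smooth_labels(seq_of(lab4))
  expect_identical(sm4$labels[c(1, 10)], c(0L, 0L))
})

test_that("the gap-fill-then-remove order is load-bearing", {
  # long run, short gap, short run, short gap, long run: gap-fill first
  # bridges everything into one event; removing short runs first would
  # leave a 0.3 s gap and two events
  lab <- c(rep(1, 8), rep(0, 3), rep(1, 2), rep(0, 3), rep(1, 8))
  sm <- smooth_labels(seq_of(lab))
  expect_equal(nrow(extract_events(sm)), 1L)

  reversed_rules <- function(s) {
    r <- rle(s$labels)
    r$values[r$values == 1L & r$lengths * 10 / 200 < 0.2] <- 0L
    s2 <- label_sequence(inverse.rle(r), s$windows)
    r <- rle(s2$labels)
    k <- length(r$lengths)
    inner <- seq_len(k) > 1 & seq_len(k) < k
    r$values[r$values == 0L & inner & r$lengths * 10 / 200 < 0.2] <- 1L
    label_sequence(inverse.rle(r), s$windows)
  }
  expect_equal(nrow(extract_events(reversed_rules(seq_of(lab)))), 2L)
})

test_that("smoothing is idempotent and leaves no short inter-event gap", {
  set.seed(16)
  for (rep in 1:200) {
    lab <- rbinom(sample(10:80, 1), 1, runif(1, 0.2, 0.8))
    s <- seq_of(lab)
    sm <- smooth_labels(s)
    expect_identical(smooth_labels(sm)$labels, sm$labels)
    r <- rle(sm$labels)
    k <- length(r$lengths)
    inner <- which(r$values == 0L & seq_len(k) > 1 & seq_len(k) < k)
    if (length(inner) > 0)
      expect_true(all(r$lengths[inner] * 10 / 200 >= 0.2))
    on <- which(r$values == 1L)
    if (length(on) > 0)
      expect_true(all(r$lengths[on] * 10 / 200 >= 0.2))
  }
})

test_that("extract_events equals a brute-force run-length oracle", {
  # spec'd anchoring on a tiny case: [0,0,1,1,1,0] at stride 1, fs 200
  s <- seq_of(c(0, 0, 1, 1, 1, 0), stride = 1L)
  ev <- extract_events(s)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_s, 2 / 200)
  expect_equal(ev$end_s, (4 + 180) / 200)

  expect_equal(nrow(extract_events(seq_of(rep(0, 20)))), 0L)

  set.seed(17)
  for (rep in 1:1000) {
    lab <- rbinom(sample(1:60, 1), 1, runif(1))
    stride <- sample(c(1L, 5L, 10L), 1)
    s <- seq_of(lab, stride = stride)
    ev <- extract_events(s)
    runs <- oracle_runs(lab)
    if (is.null(runs)) {
      expect_equal(nrow(ev), 0L)
    } else {
      expect_equal(nrow(ev), nrow(runs))
      expect_identical(ev$window_first, unname(runs[, "first"]))
      expect_identical(ev$window_last, unname(runs[, "last"]))
      expect_equal(ev$start_s, (runs[, "first"] - 1) * stride / 200,
                   ignore_attr = TRUE)
      expect_equal(ev$end_s, ((runs[, "last"] - 1) * stride + 180) / 200,
                   ignore_attr = TRUE)
    }
  }
})

test_that("center anchoring spans first-to-last window centers", {
  s <- seq_of(c(0, 1, 1, 0), stride = 10L)
  ev <- extract_events(s, anchor = "center")
  expect_equal(ev$start_s, 10 / 200 + 90 / 200)
  expect_equal(ev$end_s, 20 / 200 + 90 / 200)
})

test_that("types are assigned by mode with posterior and index tie-breaks", {
  mkpost <- function(labels, conf = 0.9) {
    p <- matrix((1 - conf) / 3, length(labels), 4,
                dimnames = list(NULL, as.character(0:3)))
    p[cbind(seq_along(labels), labels + 1)] <- conf
    p
  }
  ev <- data.frame(start_s = 0, end_s = 1, type = NA_character_, hand = "lead",
                   window_first = 1L, window_last = 3L)
  # [jab, jab, hook] -> jab
  got <- assign_types(ev, mkpost(c(1, 1, 2)))
  expect_identical(got$type, "jab")
  # no-punch windows are excluded from the mode
  ev2 <- ev; ev2$window_last <- 5L
  expect_identical(assign_types(ev2, mkpost(c(0, 0, 0, 0, 2)))$type, "hook")
  # mode tie -> higher mean posterior wins
  p <- mkpost(c(1, 1, 2, 2))
  p[1:2, "1"] <- 0.8; p[3:4, "2"] <- 0.6
  ev3 <- ev; ev3$window_last <- 4L
  expect_identical(assign_types(ev3, p)$type, "jab")
  # full tie -> lower class index wins
  expect_identical(assign_types(ev3, mkpost(c(1, 1, 3, 3)))$type, "jab")
  # single-window event takes that window's label
  ev4 <- ev; ev4$window_last <- 1L
  expect_identical(assign_types(ev4, mkpost(3))$type, "uppercut")
  # zero typed windows: unassigned with a warning
  expect_warning(got0 <- assign_types(ev, mkpost(c(0, 0, 0))), "unassigned")
  expect_true(is.na(got0$type))
})

test_that("per-type counts conserve the event total", {
  ev <- data.frame(start_s = 1:5, end_s = 2:6,
                   type = c("jab", "jab", "hook", "jab", "hook"),
                   hand = "lead")
  expect_identical(punch_type_counts(ev),
                   c(jab = 3L, hook = 2L, uppercut = 0L))
  expect_identical(punch_type_counts(ev[0, ]),
                   c(jab = 0L, hook = 0L, uppercut = 0L))
  set.seed(18)
  ev$type <- sample(c("jab", "hook", "uppercut"), 5, replace = TRUE)
  expect_equal(sum(punch_type_counts(ev)), nrow(ev))
})

test_that("the cut list maps events to half-open, monotone frame ranges", {
  stream <- imu_stream(matrix(0, 2, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))),
                       t0_utc_s = 1.7e9)
  sync <- align_clocks(stream, video_clock(1.7e9, 60))
  ev <- data.frame(start_s = c(1.0, 3.2), end_s = c(1.8, 4.0),
                   type = c("jab", "hook"), hand = "lead")
  cuts <- segment_video(ev, sync)
  expect_identical(cuts$start_frame, c(60L, 192L))
  expect_identical(cuts$end_frame, c(109L, 241L)) # floor(1.8*60)+1 = 109
  expect_true(all(diff(cuts$start_frame) >= 0))
  # round trip: each start frame's video time is at or before start_s
  expect_true(all(cuts$start_frame / 60 <= ev$start_s - sync$offset_s))

  # an event before the video start is flagged, not dropped
  sync2 <- align_clocks(stream, video_clock(1.7e9 + 2, 60))
  expect_warning(cuts2 <- segment_video(ev, sync2), "precedes")
  expect_identical(cuts2$before_video, c(TRUE, FALSE))
  expect_identical(nrow(cuts2), 2L)
  expect_true(is.na(cuts2$start_frame[1]))
})

test_that("greedy midpoint matching counts hits, misses and false alarms", {
  truth <- data.frame(start_s = c(1, 3, 5), end_s = c(1.8, 3.8, 5.8))
  det <- data.frame(start_s = c(0.9, 4.9, 7.0), end_s = c(1.9, 5.9, 7.5))
  m <- match_events(det, truth)
  expect_equal(m$n_tp, 2L)
  expect_equal(m$n_fp, 1L)
  expect_equal(m$n_fn, 1L)
})
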