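#' A per-window binary label sequence
#'
#' Predicted punch/no-punch labels aligned to window start times, carrying
#' the window geometry needed to convert run lengths to seconds.
#'
#' @param labels integer vector of 0/1 per window.
#' @param windows the [make_windows()] result the labels align to.
#' @return an object of class `label_sequence`.
#' @export
label_sequence <- function(labels, windows) {
  stopifnot(inherits(windows, "window_set"))
  labels <- as.integer(labels)
  if (length(labels) != windows$n_windows)
    stopf("labels length %d != window count %d", length(labels), windows$n_windows)
  if (length(labels) > 0L && !all(labels %in% c(0L, 1L)))
    stopf("labels must be 0/1")
  structure(list(labels = labels, windows = windows), class = "label_sequence")
}

#' Per-window punch/no-punch prediction
#'
#' Argmax of the committee posterior per window (posterior ties resolve to
#' the lower class index, i.e. no-punch).
#'
#' @param committee a fitted binary `committee` (classes `"0"`, `"1"`).
#' @param features feature data frame from [extract_features()].
#' @param windows the matching [make_windows()] result.
#' @return a [label_sequence()].
#' @export
predict_sequence <- function(committee, features, windows) {
  stopifnot(inherits(committee, "committee"))
  post <- predict_posterior(committee, feature_columns(features))
  lab <- as.integer(predict_labels(post))
  label_sequence(lab, windows)
}

# Duration in seconds of a run of `len` consecutive windows.
run_duration_s <- function(len, windows) len * windows$stride / windows$fs

#' Temporal smoothing of a predicted label sequence
#'
#' Two passes, in this order: (i) every *interior* 0-run shorter than
#' `min_gap_s` is flipped to 1, merging the flanking punch runs (a punch
#' interrupted by a blip of misclassified windows is one punch; so are two
#' punches closer than the minimum inter-punch interval); then (ii) every
#' 1-run shorter than `min_event_s` is flipped to 0 (too short to be a
#' punch). Leading/trailing 0-runs are never flipped. The procedure is
#' idempotent, and the pass order matters: removing short runs first could
#' re-open gaps that pass (i) would have bridged.
#'
#' @param seq a [label_sequence()].
#' @param min_gap_s minimum credible gap between punches, seconds (0.2).
#' @param min_event_s minimum credible punch duration, seconds (0.2).
#' @param avg_event_s nominal punch duration, seconds (0.8); carried for
#'   reporting, not used as a smoothing constraint.
#' @return the smoothed [label_sequence()] with an `avg_event_s` attribute.
#' @export
smooth_labels <- function(seq, min_gap_s = 0.2, min_event_s = 0.2,
                          avg_event_s = 0.8) {
  stopifnot(inherits(seq, "label_sequence"))
  for (v in c(min_gap_s, min_event_s, avg_event_s))
    if (!is_number(v) || v <= 0) stopf("smoothing constraints must be positive")
  lab <- seq$labels
  if (length(lab) > 0L) {
    # (i) fill short interior gaps
    r <- rle(lab)
    k <- length(r$lengths)
    interior <- seq_len(k) > 1L & seq_len(k) < k
    flip <- r$values == 0L & interior &
      run_duration_s(r$lengths, seq$windows) < min_gap_s
    r$values[flip] <- 1L
    lab <- inverse.rle(r)
    # (ii) drop short punch runs
    r <- rle(lab)
    flip <- r$values == 1L & run_duration_s(r$lengths, seq$windows) < min_event_s
    r$values[flip] <- 0L
    lab <- inverse.rle(r)
  }
  out <- label_sequence(lab, seq$windows)
  attr(out, "avg_event_s") <- avg_event_s
  out
}

#' Extract punch events from a binary label sequence
#'
#' One event per maximal run of 1's: the punch starts at the run's first
#' window's start time and ends at the run's last window's end time
#' (`anchor = "start"`, the default), or spans first-to-last window centers
#' (`anchor = "center"`). The total punch count is the number of runs.
#'
#' @param seq a (smoothed) [label_sequence()].
#' @param hand wrist tag for the emitted events.
#' @param anchor where a window's label is anchored in time.
#' @return a data frame of punch events: `start_s`, `end_s`, `type` (NA
#'   until [assign_types()]), `hand`, `window_first`, `window_last`.
#' @export
extract_events <- function(seq, hand = "lead", anchor = c("start", "center")) {
  stopifnot(inherits(seq, "label_sequence"))
  anchor <- match.arg(anchor)
  w <- seq$windows
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      type = character(), hand = character(),
                      window_first = integer(), window_last = integer())
  if (length(seq$labels) == 0L || all(seq$labels == 0L)) return(empty)
  r <- rle(seq$labels)
  ends <- cumsum(r$lengths)
  firsts <- ends - r$lengths + 1L
  on <- which(r$values == 1L)
  i <- firsts[on]
  j <- ends[on]
  half <- w$window_len / (2 * w$fs)
  if (anchor == "start") {
    start_s <- w$start_s[i]
    end_s <- w$end_s[j]
  } else {
    start_s <- w$start_s[i] + half
    end_s <- w$start_s[j] + half
  }
  data.frame(start_s = start_s, end_s = end_s, type = NA_character_,
             hand = hand, window_first = i, window_last = j)
}

#' Assign a punch type to each event by the mode of window labels
#'
#' Each event's type is the mode of the per-window multiclass argmax labels
#' over the event's windows, excluding no-punch labels. Mode ties break by
#' the higher mean posterior probability over the event's windows, then by
#' the lower class index. An event with zero typed windows keeps type `NA`
#' with a warning.
#'
#' @param events events data frame from [extract_events()].
#' @param type_posterior a `class_posterior` over classes `"0".."3"` with
#'   one row per window of the sequence the events came from.
#' @return `events` with the `type` column filled
#'   (`"jab"/"hook"/"uppercut"`).
#' @export
assign_types <- function(events, type_posterior) {
  if (nrow(events) == 0L) return(events)
  p <- unclass(type_posterior)
  cls <- colnames(type_posterior)
  lab <- cls[max.col(p, ties.method = "first")]
  for (ev in seq_len(nrow(events))) {
    idx <- events$window_first[ev]:events$window_last[ev]
    typed <- lab[idx][lab[idx] != "0"]
    if (length(typed) == 0L) {
      warnf("event %d has no punch-typed windows; type left unassigned", ev)
      next
    }
    tab <- table(typed)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
      meanpost <- vapply(cand, function(k) mean(p[idx, k]), numeric(1))
      cand <- cand[meanpost == max(meanpost)]
      cand <- cand[order(as.integer(cand))][1] # lower class index wins
    }
    events$type[ev] <- PUNCH_TYPES[as.integer(cand)]
  }
  events
}

#' Per-type punch counts
#'
#' @param events typed events data frame.
#' @return named integer vector over `jab`, `hook`, `uppercut` (and
#'   `unassigned` if any event has no type).
#' @export
punch_type_counts <- function(events) {
  counts <- stats::setNames(integer(3), PUNCH_TYPES)
  if (nrow(events) > 0L) {
    tab <- table(factor(events$type, levels = PUNCH_TYPES))
    counts[names(tab)] <- as.integer(tab)
    n_un <- sum(is.na(events$type))
    if (n_un > 0L) counts <- c(counts, unassigned = n_un)
  }
  counts
}

#' Build the video cut list for detected punches
#'
#' Maps each event's start/end to 0-based video frames through the clock
#' sync: `start_frame = floor((start_s - offset) * fps)` and
#' `end_frame = floor((end_s - offset) * fps) + 1` (half-open range). An
#' event that precedes the video start is flagged (`before_video = TRUE`,
#' frames NA) rather than silently dropped.
#'
#' @param events typed events data frame.
#' @param sync a `sync_map` from [align_clocks()].
#' @return cut-list data frame: `event_id`, `hand`, `type`, `start_s`,
#'   `end_s`, `start_frame`, `end_frame`, `before_video`.
#' @export
segment_video <- function(events, sync) {
  stopifnot(inherits(sync, "sync_map"))
  n <- nrow(events)
  out <- data.frame(event_id = seq_len(n),
                    hand = events$hand %||% rep("lead", n),
                    type = events$type,
                    start_s = events$start_s, end_s = events$end_s,
                    start_frame = NA_integer_, end_frame = NA_integer_,
                    before_video = FALSE)
  for (i in seq_len(n)) {
    if (events$start_s[i] - sync$offset_s < 0) {
      out$before_video[i] <- TRUE
      warnf("event %d precedes the video start; flagged in the cut list", i)
      next
    }
    out$start_frame[i] <- time_to_frame(events$start_s[i], sync)
    out$end_frame[i] <- time_to_frame(events$end_s[i], sync) + 1L
  }
  out
}

#' Greedy one-to-one matching of detected events to ground truth
#'
#' A detected event matches a true event when its midpoint lies inside the
#' true event's span; matching is greedy in time order and one-to-one.
#' Unmatched detections are false positives, unmatched truths false
#' negatives.
#'
#' @param detected,truth events data frames with `start_s`, `end_s`.
#' @return list with `matches` (data frame of index pairs), `n_tp`, `n_fp`,
#'   `n_fn`.
#' @export
match_events <- function(detected, truth) {
  used <- logical(nrow(truth))
  pairs <- NULL
  for (i in seq_len(nrow(detected))) {
    mid <- (detected$start_s[i] + detected$end_s[i]) / 2
    hit <- which(!used & truth$start_s <= mid & mid < truth$end_s)
    if (length(hit) > 0L) {
      used[hit[1]] <- TRUE
      pairs <- rbind(pairs, data.frame(detected = i, truth = hit[1]))
    }
  }
  n_tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(matches = pairs %||% data.frame(detected = integer(), truth = integer()),
       n_tp = n_tp, n_fp = nrow(detected) - n_tp, n_fn = sum(!used))
}
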