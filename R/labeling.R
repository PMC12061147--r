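#' Fraction of a punch falling inside a window
#'
#' Both intervals are half-open sample ranges. The denominator is the punch
#' duration (`e - s`), not the window length: a window "contains 60% of the
#' punch" when 60% of the punch's samples fall inside it.
#'
#' @param window numeric length-2 vector `c(a, b)`, the window `[a, b)`.
#' @param event numeric length-2 vector `c(s, e)`, the punch `[s, e)`.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(window, event) {
  stopifnot(length(window) == 2L, length(event) == 2L,
            window[2] > window[1], event[2] > event[1])
  max(0, min(window[2], event[2]) - max(window[1], event[1])) /
    (event[2] - event[1])
}

#' Label windows against ground-truth events by percentage overlap
#'
#' A window gets binary label 1 ("punch") when the largest fraction of any
#' single event falling inside it reaches `criterion` (default 60%), else 0.
#' Its type label is then the type of that argmax event (1 jab, 2 hook,
#' 3 uppercut; ties go to the earlier event); windows below the criterion
#' get type 0 ("no punch").
#'
#' @param windows a [make_windows()] result.
#' @param events ground-truth events data frame (`start_s, end_s, type`,
#'   one hand); overlapping events are invalid ground truth and error.
#' @param criterion overlap fraction in `[0.1, 1]` (default 0.6).
#' @return an object of class `labelled_windows`: a data frame with columns
#'   `window` (index), `y_bin` (0/1) and `y_type` (0--3), plus a
#'   `criterion` attribute.
#' @export
label_windows <- function(windows, events, criterion = 0.6) {
  stopifnot(inherits(windows, "window_set"))
  if (!is_number(criterion) || criterion < 0.1 || criterion > 1)
    stopf("criterion must be in [0.1, 1]")
  events <- as.data.frame(events)
  ne <- nrow(events)
  if (ne > 1L) {
    o <- order(events$start_s)
    ev <- events[o, ]
    if (any(ev$start_s[-1] < ev$end_s[-ne]))
      stopf("overlapping ground-truth events within one hand: invalid ground truth")
    events <- ev
  }
  nw <- windows$n_windows
  y_bin <- integer(nw)
  y_type <- integer(nw)
  if (nw > 0L && ne > 0L) {
    fs <- windows$fs
    a <- windows$starts - 1L             # 0-based window starts
    b <- a + windows$window_len
    s <- round(events$start_s * fs)
    e <- round(events$end_s * fs)
    # nw x ne overlap fractions
    frac <- sapply(seq_len(ne), function(k) {
      pmax(0, pmin(b, e[k]) - pmax(a, s[k])) / (e[k] - s[k])
    })
    frac <- matrix(frac, nrow = nw)
    best <- max.col(frac, ties.method = "first") # earlier event on ties
    bestf <- frac[cbind(seq_len(nw), best)]
    y_bin <- as.integer(bestf >= criterion)
    y_type <- ifelse(y_bin == 1L, match(events$type[best], PUNCH_TYPES), 0L)
  }
  structure(data.frame(window = seq_len(nw), y_bin = y_bin,
                       y_type = as.integer(y_type)),
            criterion = criterion, class = c("labelled_windows", "data.frame"))
}

#' Label the same windows at several overlap criteria
#'
#' The punch-labeled window sets are nested: raising the criterion can only
#' shrink the set.
#'
#' @param windows a [make_windows()] result.
#' @param events ground-truth events data frame.
#' @param criteria numeric vector of overlap fractions in `[0.1, 1]`.
#' @return named list of [label_windows()] results, one per criterion.
#' @export
criterion_sweep <- function(windows, events, criteria = seq(0.1, 1, by = 0.1)) {
  out <- lapply(criteria, function(cr) label_windows(windows, events, cr))
  names(out) <- format(criteria)
  out
}
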