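#' One wrist's 6-DoF IMU stream
#'
#' An `imu_stream` holds a single wrist sensor's timestamped 6-channel signal:
#' 3-axis accelerometer (`ax`, `ay`, `az`, in g) and 3-axis gyroscope
#' (`gx`, `gy`, `gz`, in deg/s), sampled at a fixed rate (200 Hz for the
#' wrist sensors this package targets). Sample `i` (1-based) occurs at UTC
#' time `t0_utc_s + (i - 1) / fs`; session-relative times used everywhere
#' else in the package are `(i - 1) / fs`.
#'
#' @param data numeric matrix (or data frame) with exactly the six columns
#'   `ax, ay, az, gx, gy, gz`.
#' @param fs sampling rate in samples/s; must be positive.
#' @param t0_utc_s UTC epoch time of the first sample, in seconds.
#' @param hand which wrist: `"lead"` or `"rear"`.
#' @return an object of class `imu_stream`.
#' @export
imu_stream <- function(data, fs = 200, t0_utc_s = 0, hand = "lead") {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) != 6L)
    stopf("imu_stream data must be a numeric matrix with 6 channels, got %d", ncol(data))
  if (is.null(colnames(data))) colnames(data) <- CHANNELS
  if (!identical(colnames(data), CHANNELS))
    stopf("imu_stream channels must be named %s", paste(CHANNELS, collapse = ", "))
  if (!is_number(fs) || fs <= 0) stopf("fs must be a positive number")
  if (!is_number(t0_utc_s)) stopf("t0_utc_s must be a finite number")
  hand <- match.arg(hand, HANDS)
  structure(
    list(data = data, fs = fs, t0_utc_s = t0_utc_s, hand = hand),
    class = "imu_stream"
  )
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("<imu_stream> %s hand, %d samples @ %g Hz (%.2f s), t0 = %.3f UTC\n",
              x$hand, nrow(x$data), x$fs, nrow(x$data) / x$fs, x$t0_utc_s))
  invisible(x)
}

#' @export
length.imu_stream <- function(x) nrow(x$data)

# Session-relative sample times in seconds (first sample at 0).
stream_times <- function(stream) (seq_len(nrow(stream$data)) - 1) / stream$fs

#' A video clock anchor
#'
#' The video recorder's clock is described by the UTC time of its first frame
#' and its frame rate. Frames are 0-based; frame `k` spans the half-open
#' video-time interval `[k/fps, (k+1)/fps)`.
#'
#' @param v0_utc_s UTC epoch time of the first frame, seconds.
#' @param fps frames per second; must be positive (default 60).
#' @return an object of class `video_clock`.
#' @export
video_clock <- function(v0_utc_s, fps = 60) {
  if (!is_number(v0_utc_s)) stopf("v0_utc_s must be a finite number")
  if (!is_number(fps) || fps <= 0) stopf("fps must be a positive number")
  structure(list(v0_utc_s = v0_utc_s, fps = fps), class = "video_clock")
}

#' Align the IMU clock with a video clock
#'
#' Both devices stamp their samples/frames with UTC times but start at
#' different instants. For one physical instant, session-relative IMU time
#' and video time differ by a constant offset
#' `offset_s = imu_time - video_time = v0_utc_s - t0_utc_s`: if the camera
#' started 7 ms after the sensor, the IMU session clock reads 7 ms more than
#' the video clock at every instant. Pure arithmetic; no resampling.
#'
#' @param stream an [imu_stream()].
#' @param video a [video_clock()].
#' @return an object of class `sync_map` with fields `offset_s`, `fps`, `fs`.
#' @export
align_clocks <- function(stream, video) {
  stopifnot(inherits(stream, "imu_stream"), inherits(video, "video_clock"))
  offset <- video$v0_utc_s - stream$t0_utc_s
  if (!is.finite(offset)) stopf("clock offset is not finite")
  structure(list(offset_s = offset, fps = video$fps, fs = stream$fs),
            class = "sync_map")
}

#' Map a session-relative IMU time to a 0-based video frame index
#'
#' `frame = floor((t_imu_s - offset_s) * fps)`. Monotone non-decreasing in
#' `t_imu_s`.
#'
#' @param t_imu_s session-relative IMU time(s), seconds; vectorized.
#' @param sync a `sync_map` from [align_clocks()].
#' @return integer frame index (0-based) per input time.
#' @export
time_to_frame <- function(t_imu_s, sync) {
  stopifnot(inherits(sync, "sync_map"))
  vt <- t_imu_s - sync$offset_s
  if (any(vt < 0)) stopf("time precedes video start (negative video time)")
  as.integer(floor(vt * sync$fps))
}

#' Read an IMU stream from CSV
#'
#' Expects the dialect `t_utc_s,ax,ay,az,gx,gy,gz,hand` with one row per
#' sample and monotonically increasing timestamps. The sampling rate is
#' inferred from the median timestamp spacing rather than trusted metadata;
#' if `expected_fs` is given and the inferred rate deviates by more than 1%,
#' a warning (not an error) is raised.
#'
#' @param path CSV file path.
#' @param expected_fs optional nominal sampling rate to check against.
#' @return an [imu_stream()].
#' @export
read_imu_csv <- function(path, expected_fs = NULL) {
  if (!file.exists(path)) stopf("IMU CSV not found: %s", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stopf("empty or unreadable IMU CSV: %s", path))
  if (nrow(df) == 0L) stopf("empty IMU CSV (no samples): %s", path)
  missing <- setdiff(setdiff(IMU_CSV_COLS, "hand"), names(df))
  if (length(missing) > 0L)
    stopf("IMU CSV missing required column(s): %s", paste(missing, collapse = ", "))
  t <- df$t_utc_s
  if (nrow(df) > 1L && any(diff(t) <= 0))
    stopf("non-monotone timestamps in IMU CSV (rows out of order?)")
  fs <- if (nrow(df) > 1L) 1 / stats::median(diff(t)) else (expected_fs %||% 200)
  if (!is.null(expected_fs) && abs(fs - expected_fs) / expected_fs > 0.01)
    warnf("inferred sampling rate %.2f Hz differs from expected %.2f Hz by > 1%%",
          fs, expected_fs)
  hand <- if ("hand" %in% names(df)) unique(df$hand)[1] else "lead"
  imu_stream(as.matrix(df[, CHANNELS]), fs = fs, t0_utc_s = t[1], hand = hand)
}

#' Write an IMU stream to CSV
#'
#' Inverse of [read_imu_csv()]; round-trips losslessly to at least 9 decimal
#' places.
#'
#' @param stream an [imu_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  stopifnot(inherits(stream, "imu_stream"))
  t <- stream$t0_utc_s + stream_times(stream)
  # epoch timestamps need fixed 9-decimal printing (15 significant digits
  # would lose ~10 us at epoch scale); channels round-trip at %.12g
  df <- data.frame(t_utc_s = sprintf("%.9f", t),
                   apply(stream$data, 2, function(x) sprintf("%.12g", x)),
                   hand = stream$hand, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write punch events as JSON
#'
#' Events are an array of objects `{start_s, end_s, type, hand}`, times in
#' session-relative seconds. An empty event list is a valid empty array.
#'
#' @param events a data frame with columns `start_s`, `end_s`, `type`, `hand`.
#' @param path JSON file path.
#' @return `read_events_json` returns the events data frame; `write_events_json`
#'   returns `path` invisibly.
#' @export
write_events_json <- function(events, path) {
  events <- as.data.frame(events)[, c("start_s", "end_s", "type", "hand")]
  jsonlite::write_json(events, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_events_json
#' @export
read_events_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(x) == 0L)
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      type = character(), hand = character()))
  as.data.frame(x)[, c("start_s", "end_s", "type", "hand")]
}

#' Write a video cut list to CSV
#'
#' One row per punch event with its session times and 0-based half-open
#' frame range `[start_frame, end_frame)`.
#'
#' @param cuts cut-list data frame from [segment_video()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cut_list <- function(cuts, path) {
  cols <- c("event_id", "hand", "type", "start_s", "end_s",
            "start_frame", "end_frame")
  utils::write.csv(as.data.frame(cuts)[, cols], path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
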