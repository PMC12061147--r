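#' Configuration for a synthetic shadowboxing session
#'
#' Describes the session the generator emulates: a boxer throwing
#' `n_punches` punches of mixed type at a wrist sensor sampling at `fs` Hz,
#' with punch durations around `punch_duration_s` (0.8 s nominal, jitter
#' reaching ~0.9 s), background guard/bounce motion between punches, and an
#' optional fraction of rapid combinations whose inter-punch gap is at most
#' 0.2 s.
#'
#' @param duration_s session length in seconds.
#' @param fs sampling rate, samples/s (default 200).
#' @param n_punches number of punches to place.
#' @param type_mix named probability per type (`jab`, `hook`, `uppercut`);
#'   non-negative, sums to 1.
#' @param punch_duration_s mean punch duration, seconds (default 0.8).
#' @param punch_jitter_s half-width of the uniform duration jitter (default
#'   0.1, so durations span 0.7--0.9 s).
#' @param min_gap_s minimum gap between consecutive non-combo punches,
#'   seconds (default 0.5).
#' @param combo_prob probability that a punch is followed by the next within
#'   at most 0.2 s (a combination), default 0.
#' @param noise_sd white sensor-noise standard deviation in accelerometer
#'   units (g); gyro noise is scaled by 50.
#' @param hand wrist tag, `"lead"` or `"rear"`.
#' @param t0_utc_s UTC epoch time of the first sample.
#' @param seed integer RNG seed; the same config yields a bit-identical
#'   session.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s, n_punches,
                             fs = 200,
                             type_mix = c(jab = 1/3, hook = 1/3, uppercut = 1/3),
                             punch_duration_s = 0.8,
                             punch_jitter_s = 0.1,
                             min_gap_s = 0.5,
                             combo_prob = 0,
                             noise_sd = 0.3,
                             hand = "lead",
                             t0_utc_s = 1.7e9,
                             seed = 1L) {
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be positive")
  if (!is_number(fs) || fs <= 0) stopf("fs must be positive")
  if (!is_count(n_punches)) stopf("n_punches must be a non-negative integer")
  if (length(type_mix) != 3L || is.null(names(type_mix)) ||
      !setequal(names(type_mix), PUNCH_TYPES))
    stopf("type_mix must be named probabilities for %s", paste(PUNCH_TYPES, collapse = ", "))
  type_mix <- type_mix[PUNCH_TYPES]
  if (any(type_mix < 0) || abs(sum(type_mix) - 1) > 1e-9)
    stopf("type_mix entries must be >= 0 and sum to 1")
  if (!is_number(punch_duration_s) || punch_duration_s <= 0)
    stopf("punch_duration_s must be positive")
  if (punch_jitter_s < 0 || punch_jitter_s >= punch_duration_s)
    stopf("punch_jitter_s must be in [0, punch_duration_s)")
  if (!is_number(min_gap_s) || min_gap_s < 0) stopf("min_gap_s must be >= 0")
  if (!is_number(combo_prob) || combo_prob < 0 || combo_prob > 1)
    stopf("combo_prob must be in [0, 1]")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  hand <- match.arg(hand, HANDS)
  structure(list(duration_s = duration_s, fs = fs, n_punches = as.integer(n_punches),
                 type_mix = type_mix, punch_duration_s = punch_duration_s,
                 punch_jitter_s = punch_jitter_s, min_gap_s = min_gap_s,
                 combo_prob = combo_prob, noise_sd = noise_sd, hand = hand,
                 t0_utc_s = t0_utc_s, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Peak dominant-axis acceleration of a punch template, in g. Background
# motion is scaled to stay below 20% of this.
PUNCH_PEAK_G <- 8
PUNCH_PEAK_DPS <- 600

#' Generate one punch's 6-channel waveform template
#'
#' The template is a half-sine acceleration burst on the punch type's
#' dominant axis (x for jabs, y for hooks, z for uppercuts -- straight,
#' lateral-arc and upward-arc punches respectively), a smaller full-sine
#' component on the two remaining axes, and a correlated half-sine gyroscope
#' burst. The waveform is zero-anchored at both ends (the fist starts and
#' ends near rest), and the dominant accelerometer axis carries strictly the
#' largest signal energy of the three.
#'
#' @param type `"jab"`, `"hook"` or `"uppercut"`.
#' @param duration_s punch duration, seconds; must be positive.
#' @param fs sampling rate, samples/s.
#' @param seed optional seed for the +/-10% amplitude jitter; `NULL` uses the
#'   current RNG stream.
#' @return a `round(duration_s * fs)` x 6 matrix with columns
#'   `ax, ay, az, gx, gy, gz`.
#' @export
punch_template <- function(type, duration_s, fs = 200, seed = NULL) {
  if (!type %in% PUNCH_TYPES)
    stopf("unknown punch type '%s'; valid types: %s", type,
          paste(PUNCH_TYPES, collapse = ", "))
  if (!is_number(duration_s) || duration_s <= 0)
    stopf("duration_s must be positive, got %s", format(duration_s))
  n <- round(duration_s * fs)
  if (n < 2L) stopf("duration_s too short for sampling rate (%d samples)", n)
  with_seed(seed, {
    u <- seq(0, 1, length.out = n)
    main <- PUNCH_PEAK_G * stats::runif(1, 0.9, 1.1) * sin(pi * u)
    side <- 1.5 * stats::runif(1, 0.9, 1.1) * sin(2 * pi * u)
    dom <- match(type, PUNCH_TYPES) # 1 = x, 2 = y, 3 = z
    acc <- matrix(0, n, 3)
    acc[, dom] <- main
    others <- setdiff(1:3, dom)
    acc[, others[1]] <- side
    acc[, others[2]] <- -0.8 * side
    gyr <- matrix(0, n, 3)
    gmain <- PUNCH_PEAK_DPS * stats::runif(1, 0.9, 1.1) * sin(pi * u)
    gyr[, dom] <- gmain
    gyr[, others[1]] <- 0.3 * gmain
    out <- cbind(acc, gyr)
    colnames(out) <- CHANNELS
    out
  })
}

#' Generate a synthetic session with ground-truth punch annotations
#'
#' Places `n_punches` punch templates in a `duration_s`-second stream,
#' separated by at least `min_gap_s` (or by a gap of at most 0.2 s when a
#' punch is sampled as part of a combination), over low-amplitude
#' band-limited background motion (< 5 Hz, peak under 20% of the punch peak)
#' plus white sensor noise. Errors rather than truncating if the events do
#' not fit. The same config (including seed) yields a bit-identical session.
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `stream` (an [imu_stream()]) and `events`
#'   (a data frame `start_s, end_s, type, hand`, sorted, non-overlapping).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_total <- round(config$duration_s * config$fs)
  with_seed(config$seed, {
    np <- config$n_punches
    pad <- min(1, config$duration_s / 10)
    if (np > 0L) {
      durs <- stats::runif(np, config$punch_duration_s - config$punch_jitter_s,
                           config$punch_duration_s + config$punch_jitter_s)
      combo <- if (np > 1L)
        stats::runif(np - 1L) < config$combo_prob else logical(0)
      gaps <- ifelse(combo, stats::runif(np - 1L, 0.05, 0.2),
                     config$min_gap_s)
      slack <- config$duration_s - 2 * pad - sum(durs) - sum(gaps)
      if (slack < 0)
        stopf("infeasible placement: %d punches need %.2f s but session is %.2f s",
              np, sum(durs) + sum(gaps) + 2 * pad, config$duration_s)
      # spread the slack over the leading pad and the non-combo gaps so
      # events cover the whole session rather than bunching at the start
      free <- c(TRUE, !combo)
      w <- stats::runif(np)
      w[!free] <- 0
      extra <- if (sum(w) > 0) slack * 0.9 * w / sum(w) else rep(0, np)
      starts <- pad + cumsum(extra + c(0, durs[-np] + gaps))
      types <- sample(PUNCH_TYPES, np, replace = TRUE, prob = config$type_mix)
      events <- data.frame(start_s = starts, end_s = starts + durs,
                           type = types, hand = config$hand,
                           stringsAsFactors = FALSE)
    } else {
      events <- data.frame(start_s = numeric(), end_s = numeric(),
                           type = character(), hand = character())
    }

    # background guard/bounce motion: band-limited (< 5 Hz) noise at under
    # 20% of the punch peak, plus white sensor noise
    bf <- signal::butter(2, min(5 / (config$fs / 2), 0.95), type = "low")
    bg_amp <- c(rep(0.15 * PUNCH_PEAK_G, 3), rep(0.15 * PUNCH_PEAK_DPS, 3))
    x <- matrix(0, n_total, 6)
    for (j in 1:6) {
      b <- signal::filtfilt(bf, stats::rnorm(n_total))
      s <- stats::sd(b)
      if (s > 0) b <- b / s * (bg_amp[j] / 3) # ~3 sd within the 20% peak cap
      x[, j] <- b + stats::rnorm(n_total, sd = config$noise_sd * ifelse(j <= 3, 1, 50))
    }
    if (nrow(events) > 0L) {
      for (i in seq_len(nrow(events))) {
        tpl <- punch_template(events$type[i],
                              events$end_s[i] - events$start_s[i], config$fs)
        i0 <- round(events$start_s[i] * config$fs) + 1L
        idx <- i0:min(i0 + nrow(tpl) - 1L, n_total)
        x[idx, ] <- x[idx, ] + tpl[seq_along(idx), , drop = FALSE]
      }
    }
    colnames(x) <- CHANNELS
    list(stream = imu_stream(x, fs = config$fs, t0_utc_s = config$t0_utc_s,
                             hand = config$hand),
         events = events)
  })
}

#' Write a session fixture (IMU CSV + events JSON) to a directory
#'
#' @param stream an [imu_stream()].
#' @param events ground-truth events data frame.
#' @param dir_path output directory; created if absent.
#' @return named character vector of the two file paths, invisibly.
#' @export
write_fixture <- function(stream, events, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  imu_path <- file.path(dir_path, "imu.csv")
  ev_path <- file.path(dir_path, "events.json")
  write_imu_csv(stream, imu_path)
  write_events_json(events, ev_path)
  invisible(c(imu = imu_path, events = ev_path))
}
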