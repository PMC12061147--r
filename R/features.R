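#' Sliding windows over an IMU stream
#'
#' Windows are half-open sample-index ranges `[start, start + window_len)`
#' laid out every `stride` samples. The defaults (180 samples, stride 1,
#' i.e. a 179-sample overlap at 200 Hz) give one window per sample and a
#' window spanning 0.9 s -- the upper range of a punch's duration.
#'
#' @param stream an [imu_stream()].
#' @param window_len window length in samples (>= 2, default 180).
#' @param stride hop between window starts in samples (default 1);
#'   `1 <= stride <= window_len`.
#' @return an object of class `window_set` with 1-based window start indices
#'   and session-relative start/end times per window. A stream shorter than
#'   `window_len` yields an empty set with a warning.
#' @export
make_windows <- function(stream, window_len = 180L, stride = 1L) {
  stopifnot(inherits(stream, "imu_stream"))
  if (!is_count(window_len, 2L)) stopf("window_len must be an integer >= 2")
  if (!is_count(stride, 1L) || stride > window_len)
    stopf("stride must be an integer in [1, window_len]")
  n <- nrow(stream$data)
  if (n < window_len) {
    warnf("stream has %d samples, shorter than window_len = %d: no windows", n, window_len)
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, n - window_len + 1L, by = stride)
  }
  structure(list(starts = as.integer(starts),
                 window_len = as.integer(window_len),
                 stride = as.integer(stride),
                 fs = stream$fs,
                 n_windows = length(starts),
                 start_s = (starts - 1) / stream$fs,
                 end_s = (starts - 1 + window_len) / stream$fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples, stride %d @ %g Hz\n",
              x$n_windows, x$window_len, x$stride, x$fs))
  invisible(x)
}

# Shannon entropy (bits) of a 16-bin histogram of the values; a constant
# window has zero entropy by convention.
signal_entropy <- function(x, bins = 16L) {
  r <- range(x)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0) return(0)
  breaks <- seq(r[1], r[2], length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

# Moment-based skewness and excess kurtosis; zero-variance windows map to 0.
moment_skew_kurt <- function(x) {
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(c(skew = 0, kurt = 0))
  c(skew = mean(d^3) / m2^1.5, kurt = mean(d^4) / m2^2 - 3)
}

TD_STATS <- c("mean", "sd", "max", "min", "iqr", "entropy", "skew", "kurt", "mad")

#' Time-domain statistics of one window
#'
#' Per channel: mean, standard deviation, max, min, interquartile range,
#' signal entropy (Shannon entropy of a 16-bin histogram, bits), skewness,
#' excess kurtosis, and mean absolute deviation (around the mean).
#' Degenerate (constant) channels yield 0 for sd/IQR/MAD/entropy/skew/kurt,
#' never NaN.
#'
#' @param window numeric matrix, samples x 6 channels.
#' @return named numeric vector of length 54 (`ax_mean`, `ax_sd`, ...).
#' @export
time_domain_features <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) < 2L) stopf("window must have >= 2 samples")
  out <- lapply(seq_len(ncol(window)), function(j) {
    x <- window[, j]
    sk <- moment_skew_kurt(x)
    c(mean = mean(x), sd = stats::sd(x), max = max(x), min = min(x),
      iqr = stats::IQR(x), entropy = signal_entropy(x),
      skew = unname(sk["skew"]), kurt = unname(sk["kurt"]),
      mad = mean(abs(x - mean(x))))
  })
  names(out) <- colnames(window) %||% CHANNELS
  v <- unlist(out)
  names(v) <- as.vector(t(outer(names(out), TD_STATS, paste, sep = "_")))
  v
}

#' Welch power spectral density estimate
#'
#' Mean-detrended, Hann-tapered, 50%-overlapping segments of length
#' `min(64, length(x))`, averaged modified periodograms, one-sided density
#' normalization (total power `sum(psd) * df` approximates the signal
#' variance).
#'
#' @param x numeric vector.
#' @param fs sampling rate, samples/s.
#' @param seg_len segment length (default `min(64, length(x))`).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_len = min(64L, length(x)), overlap = 0.5) {
  if (!is_number(fs) || fs <= 0) stopf("fs must be positive")
  n <- length(x)
  if (n < 8L) stopf("welch_psd needs at least 8 samples")
  m <- min(seg_len, n)
  hop <- max(1L, floor(m * (1 - overlap)))
  starts <- seq.int(1L, n - m + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / (m - 1)) # Hann taper
  scale <- 1 / (fs * sum(h^2))
  nf <- floor(m / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + m - 1L)]
    seg <- (seg - mean(seg)) * h
    p <- abs(stats::fft(seg))^2 * scale
    p <- p[1:nf]
    # one-sided: double all bins except DC and (for even m) Nyquist
    dbl <- 2:(nf - if (m %% 2 == 0) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1L)) * fs / m, psd = acc / length(starts))
}

FD_STATS <- c("pow_total", "domfreq", "bp_low", "bp_mid", "bp_high")

#' Frequency-domain summaries of one window
#'
#' Per channel, from the Welch PSD: total power (integrated density),
#' dominant frequency (Hz, at the PSD maximum; 0 for an all-zero channel),
#' and band powers over 0--5, 5--15 and 15--50 Hz (posture/guard, punch
#' motion, impact content). All-zero input yields all-zero features.
#'
#' @param window numeric matrix, samples x 6 channels; >= 8 samples.
#' @param fs sampling rate, samples/s.
#' @param bands band edges in Hz, length 4 (default `c(0, 5, 15, 50)`).
#' @return named numeric vector of length 30 (`ax_pow_total`, ...).
#' @export
frequency_domain_features <- function(window, fs, bands = c(0, 5, 15, 50)) {
  window <- as.matrix(window)
  if (!is_number(fs) || fs <= 0) stopf("fs must be positive")
  if (nrow(window) < 8L) stopf("window must have >= 8 samples")
  stopifnot(length(bands) == 4L, !is.unsorted(bands))
  out <- lapply(seq_len(ncol(window)), function(j) {
    w <- welch_psd(window[, j], fs)
    df <- w$freq[2] - w$freq[1]
    tot <- sum(w$psd) * df
    domf <- if (tot > 0) w$freq[which.max(w$psd)] else 0
    bp <- vapply(1:3, function(b) {
      sel <- w$freq >= bands[b] & w$freq < bands[b + 1]
      sum(w$psd[sel]) * df
    }, numeric(1))
    c(pow_total = tot, domfreq = domf,
      bp_low = bp[1], bp_mid = bp[2], bp_high = bp[3])
  })
  names(out) <- colnames(window) %||% CHANNELS
  v <- unlist(out)
  names(v) <- as.vector(t(outer(names(out), FD_STATS, paste, sep = "_")))
  v
}

#' Extract the per-window feature matrix of a stream
#'
#' Row `i` holds window `i`'s 84 features (6 channels x (9 time-domain + 5
#' frequency-domain)), preceded by the window's session-relative start and
#' end times. No row ever contains NaN or Inf, including constant and
#' all-zero windows.
#'
#' @param stream an [imu_stream()].
#' @param windows a [make_windows()] result; built with the defaults when
#'   omitted.
#' @param bands spectral band edges, see [frequency_domain_features()].
#' @return a data frame: `window_start_s`, `window_end_s`, then the 84
#'   feature columns with stable names.
#' @export
extract_features <- function(stream, windows = NULL, bands = c(0, 5, 15, 50)) {
  stopifnot(inherits(stream, "imu_stream"))
  if (is.null(windows)) windows <- make_windows(stream)
  stopifnot(inherits(windows, "window_set"))
  L <- windows$window_len
  feat <- lapply(windows$starts, function(s) {
    w <- stream$data[s:(s + L - 1L), , drop = FALSE]
    c(time_domain_features(w), frequency_domain_features(w, stream$fs, bands))
  })
  if (length(feat) == 0L) {
    # preserve the schema even for an empty window set
    proto <- c(time_domain_features(matrix(0, max(8L, L), 6,
                                           dimnames = list(NULL, CHANNELS))),
               frequency_domain_features(matrix(0, max(8L, L), 6,
                                                dimnames = list(NULL, CHANNELS)),
                                         stream$fs, bands))
    m <- matrix(numeric(0), 0, length(proto), dimnames = list(NULL, names(proto)))
  } else {
    m <- do.call(rbind, feat)
  }
  cbind(data.frame(window_start_s = windows$start_s,
                   window_end_s = windows$end_s),
        as.data.frame(m))
}

# Strip the window-time columns, keeping only model features.
feature_columns <- function(features) {
  as.matrix(features[, setdiff(names(features),
                               c("window_start_s", "window_end_s")), drop = FALSE])
}

#' Write a feature matrix (plus optional labels) to CSV
#'
#' @param features data frame from [extract_features()].
#' @param path output CSV path.
#' @param labels optional [label_windows()] result; appends `y_bin,y_type`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, labels = NULL) {
  df <- features
  if (!is.null(labels)) {
    df$y_bin <- labels$y_bin
    df$y_type <- labels$y_type
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
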