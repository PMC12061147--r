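# Shared fixtures, generated in code and cached per test run so expensive
# feature extractions happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small session and its feature/label set at stride 10 (keeps welch calls
# per session in the hundreds).
session_fixture <- function(seed, duration_s = 30, n_punches = 8,
                            min_gap_s = 0.5, stride = 10L) {
  cached(sprintf("ses_%d_%g_%d_%g_%d", seed, duration_s, n_punches,
                 min_gap_s, stride), {
    ses <- generate_session(synthetic_config(duration_s = duration_s,
                                             n_punches = n_punches,
                                             min_gap_s = min_gap_s,
                                             seed = seed))
    w <- make_windows(ses$stream, 180L, stride)
    f <- extract_features(ses$stream, w)
    l <- label_windows(w, ses$events)
    list(session = ses, windows = w, features = f, labels = l,
         x = as.matrix(f[, setdiff(names(f), c("window_start_s", "window_end_s"))]))
  })
}

# A committee trained on the full labels of the seed-1 session: the
# detection upper bound reused by the event and acceptance tests.
full_committee_fixture <- function(task = c("binary", "type")) {
  task <- match.arg(task)
  cached(paste0("full_committee_", task), {
    fx <- session_fixture(1L)
    y <- if (task == "binary") fx$labels$y_bin else fx$labels$y_type
    fit_committee(fx$x, y)
  })
}

# A window_set with exactly n windows (backed by a zero stream).
make_windowset <- function(n, window_len = 180L, stride = 10L, fs = 200) {
  stream <- imu_stream(matrix(0, window_len + (n - 1L) * stride, 6,
                              dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))),
                       fs = fs)
  make_windows(stream, window_len, stride)
}

# Independent spectral oracle: raw periodogram via stats::spec.pgram
# (a different code path than the package's Welch estimator).
oracle_axis_power <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  sum(sp$spec)
}

oracle_dominant_freq <- function(x, fs) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = TRUE, plot = FALSE)
  sp$freq[which.max(sp$spec)]
}

# Held-out benchmark of QBC vs random sampling vs an 80%-labeled committee
# on the binary recognition task, across seeded session pairs. Cached: the
# module test and the acceptance test assert on the same computation.
al_benchmark <- function(seeds = 1:10) {
  cached(paste0("al_benchmark_", paste(range(seeds), collapse = "_")), {
    t(vapply(seeds, function(seed) {
      pool <- session_fixture(seed, duration_s = 30, n_punches = 8)
      held <- session_fixture(seed + 500L, duration_s = 30, n_punches = 8)
      qbc <- qbc_loop(pool$x, simulated_oracle(pool$labels$y_bin), seed = seed,
                      strata = pool$labels$y_bin,
                      eval_x = held$x, eval_y = held$labels$y_bin)
      rnd <- qbc_loop(pool$x, simulated_oracle(pool$labels$y_bin), seed = seed,
                      strata = pool$labels$y_bin, strategy = "random",
                      eval_x = held$x, eval_y = held$labels$y_bin)
      i80 <- withr::with_seed(seed, sample(nrow(pool$x), round(0.8 * nrow(pool$x))))
      c80 <- fit_committee(pool$x[i80, ], pool$labels$y_bin[i80])
      acc80 <- mean(as.integer(predict_labels(predict_posterior(c80, held$x)))
                    == held$labels$y_bin)
      c(qbc5 = qbc$state$history$accuracy[1],
        qbc15 = utils::tail(qbc$state$history$accuracy, 1),
        rnd15 = utils::tail(rnd$state$history$accuracy, 1),
        acc80 = acc80)
    }, numeric(4)))
  })
}

# Brute-force run extraction oracle: scan the label vector index by index.
oracle_runs <- function(labels) {
  runs <- NULL
  i <- 1L
  n <- length(labels)
  while (i <= n) {
    if (labels[i] == 1L) {
      j <- i
      while (j < n && labels[j + 1L] == 1L) j <- j + 1L
      runs <- rbind(runs, c(first = i, last = j))
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}
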