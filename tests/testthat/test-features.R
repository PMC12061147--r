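rand_stream <- function(n, fs = 200, seed = 1) {
  set.seed(seed)
  imu_stream(matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))),
             fs = fs)
}

test_that("window counts follow the half-open sliding-window arithmetic", {
  expect_equal(make_windows(rand_stream(200), 180, 1)$n_windows, 21L)
  expect_warning(w0 <- make_windows(rand_stream(179), 180, 1), "shorter")
  expect_equal(w0$n_windows, 0L)
  w2 <- make_windows(rand_stream(360), 180, 180)
  expect_equal(w2$n_windows, 2L)
  expect_identical(w2$starts, c(1L, 181L))
  expect_error(make_windows(rand_stream(200), 1), "window_len")
  expect_error(make_windows(rand_stream(200), 180, 181), "stride")
})

test_that("time-domain statistics match closed forms and conventions", {
  const <- matrix(3.5, 50, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  v <- time_domain_features(const)
  expect_equal(unname(v["ax_mean"]), 3.5)
  for (stat in c("sd", "iqr", "mad", "entropy", "skew", "kurt"))
    expect_equal(unname(v[paste0("ax_", stat)]), 0)
  expect_equal(unname(v["ax_max"]), 3.5)
  expect_equal(unname(v["ax_min"]), 3.5)

  w <- const
  w[1:4, 1] <- c(1, 2, 3, 4)
  w <- w[1:4, ]
  v <- time_domain_features(w)
  expect_equal(unname(v["ax_mean"]), 2.5)
  expect_equal(unname(v["ax_mad"]), 1.0) # mean(|1,2,3,4 - 2.5|)

  r <- rand_stream(100)$data
  v <- time_domain_features(r)
  for (ch in c("ax","ay","az","gx","gy","gz")) {
    expect_gte(v[paste0(ch, "_max")], v[paste0(ch, "_mean")])
    expect_gte(v[paste0(ch, "_mean")], v[paste0(ch, "_min")])
  }
})

test_that("spectral features find a sinusoid's frequency and obey Parseval", {
  t <- (0:179) / 200
  w <- matrix(0, 180, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz")))
  w[, 1] <- sin(2 * pi * 10 * t)
  v <- frequency_domain_features(w, 200)
  bin <- 200 / 64 # Welch frequency resolution at segment length 64
  expect_lte(abs(v["ax_domfreq"] - 10), bin)
  expect_lte(abs(v["ax_domfreq"] - oracle_dominant_freq(w[, 1], 200)), bin)
  # the 10 Hz line lives in the 5-15 Hz band
  expect_gt(v["ax_bp_mid"], v["ax_bp_low"])
  expect_gt(v["ax_bp_mid"], v["ax_bp_high"])

  # zero signal: all spectral features 0
  vz <- frequency_domain_features(w * 0, 200)
  expect_true(all(vz == 0))

  # Parseval: white-noise total power approximates the sample variance
  # (1024-sample windows give ~31 averaged segments, so the estimator's
  # own spread sits well inside the 10% band)
  set.seed(9)
  wl <- matrix(0, 1024, 6, dimnames = dimnames(w))
  for (rep in 1:5) {
    x <- rnorm(1024)
    wl[, 1] <- x
    v <- frequency_domain_features(wl, 200)
    expect_lt(abs(v["ax_pow_total"] - var(x)) / var(x), 0.10)
  }
  expect_error(frequency_domain_features(w, -1), "fs")
})

test_that("extract_features has the documented shape and no NaN/Inf anywhere", {
  s <- rand_stream(200)
  f <- extract_features(s)
  expect_equal(nrow(f), 21L)
  expect_equal(ncol(f), 2 + 6 * (9 + 5))
  expect_identical(names(f)[1:2], c("window_start_s", "window_end_s"))
  expect_true(all(is.finite(as.matrix(f))))

  # degenerate stream: constant everywhere, still finite
  s0 <- imu_stream(matrix(1, 200, 6, dimnames = list(NULL, c("ax","ay","az","gx","gy","gz"))))
  f0 <- extract_features(s0)
  expect_true(all(is.finite(as.matrix(f0))))
})

test_that("features are shift-equivariant along the stream", {
  s <- rand_stream(260, seed = 4)
  f <- extract_features(s, make_windows(s, 180, 10))
  shifted <- imu_stream(s$data[11:260, ], fs = s$fs)
  f2 <- extract_features(shifted, make_windows(shifted, 180, 10))
  expect_equal(as.numeric(f[2, -(1:2)]), as.numeric(f2[1, -(1:2)]))
})

test_that("channel scaling acts on features as documented", {
  s <- rand_stream(180, seed = 5)
  a <- 2.5
  s2 <- s
  s2$data[, "ax"] <- a * s$data[, "ax"]
  f1 <- extract_features(s, make_windows(s, 180, 1))
  f2 <- extract_features(s2, make_windows(s2, 180, 1))
  for (stat in c("mean", "sd", "max", "min", "iqr", "mad"))
    expect_equal(f2[[paste0("ax_", stat)]], a * f1[[paste0("ax_", stat)]])
  for (stat in c("skew", "kurt"))
    expect_equal(f2[[paste0("ax_", stat)]], f1[[paste0("ax_", stat)]])
  expect_equal(f2$ax_pow_total, a^2 * f1$ax_pow_total)
  # untouched channels unchanged
  expect_equal(f2$ay_sd, f1$ay_sd)
})

test_that("permuting channels permutes only the matching column blocks", {
  s <- rand_stream(190, seed = 6)
  sw <- s
  sw$data[, c("ax", "ay")] <- s$data[, c("ay", "ax")]
  f1 <- extract_features(s, make_windows(s, 180, 5))
  f2 <- extract_features(sw, make_windows(sw, 180, 5))
  for (stat in c(c("mean","sd","max","min","iqr","entropy","skew","kurt","mad"),
                 c("pow_total","domfreq","bp_low","bp_mid","bp_high"))) {
    expect_equal(f2[[paste0("ax_", stat)]], f1[[paste0("ay_", stat)]])
    expect_equal(f2[[paste0("ay_", stat)]], f1[[paste0("ax_", stat)]])
    expect_equal(f2[[paste0("gz_", stat)]], f1[[paste0("gz_", stat)]])
  }
})

test_that("welch_psd agrees with an independent periodogram on band location", {
  set.seed(31)
  for (f0 in c(5, 25, 60)) {
    x <- sin(2 * pi * f0 * (0:255) / 200) + rnorm(256, sd = 0.1)
    w <- welch_psd(x, 200)
    expect_lte(abs(w$freq[which.max(w$psd)] - oracle_dominant_freq(x, 200)),
               200 / 64)
  }
})
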