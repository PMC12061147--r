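cn <- function(...) { m <- cbind(...); colnames(m) <- paste0("f", seq_len(ncol(m))); m }

test_that("impurity measures hit their closed forms", {
  expect_equal(gini_impurity(c(1, 0)), 0)
  expect_equal(entropy_impurity(c(1, 0)), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(entropy_impurity(c(0.5, 0.5)), 1)
  expect_equal(entropy_impurity(rep(1/3, 3)), log2(3))
})

test_that("naive Bayes posterior reduces to the priors under identical likelihoods", {
  # both classes have ML mean 0 and ML variance 1 on the single feature
  x <- cn(c(rep(c(-1, 1), 45), rep(c(-1, 1), 5)))
  y <- c(rep("a", 90), rep("b", 10))
  m <- fit_naive_bayes(x, y)
  p <- predict_posterior(m, cn(0.3))
  expect_equal(unname(p[1, ]), c(0.9, 0.1), tolerance = 1e-12)

  # single-class training: posterior 1 everywhere
  m1 <- fit_naive_bayes(cn(rnorm(5)), rep("a", 5))
  expect_equal(unname(predict_posterior(m1, cn(c(0, 10)))[, "a"]), c(1, 1))

  # requesting a class with no training samples errors, naming it
  expect_error(fit_naive_bayes(cn(1:4), rep("a", 4), classes = c("a", "b")),
               "absent.*b")
})

test_that("naive Bayes separates well-separated clusters perfectly", {
  set.seed(21)
  x <- cn(c(rnorm(40, 0, 0.5), rnorm(40, 10, 0.5)),
          c(rnorm(40, 5, 0.5), rnorm(40, -5, 0.5)))
  y <- rep(c("lo", "hi"), each = 40)
  m <- fit_naive_bayes(x, y)
  expect_identical(predict_labels(predict_posterior(m, x)), y)
})

test_that("tree member splits where exhaustive Gini search says it should", {
  set.seed(5)
  x1 <- c(runif(60, 0, 1), runif(60, 2, 3))
  y <- rep(c("a", "b"), each = 60)
  m <- fit_tree(cn(x1), y, tree_config(max_splits = 100, criterion = "gini"))
  tree_thr <- m$fit$splits[1, "index"]

  # oracle: brute-force all midpoint thresholds, minimize weighted Gini
  xs <- sort(x1)
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  wgini <- vapply(mids, function(thr) {
    l <- y[x1 <= thr]; r <- y[x1 > thr]
    gl <- gini_impurity(table(factor(l, levels = c("a","b"))) / length(l))
    gr <- gini_impurity(table(factor(r, levels = c("a","b"))) / length(r))
    (length(l) * gl + length(r) * gr) / length(y)
  }, numeric(1))
  best <- which.min(wgini)
  # the fitted threshold lies within one grid point of the oracle's
  pos <- which.min(abs(mids - tree_thr))
  expect_lte(abs(pos - best), 1)
  # and training predictions are perfect on this separable set
  expect_identical(predict_labels(predict_posterior(m, cn(x1))), y)
})

test_that("tree training error is non-increasing in max_splits", {
  set.seed(6)
  x <- cn(rnorm(200), rnorm(200))
  y <- ifelse(x[, 1] + 0.8 * sin(3 * x[, 2]) + rnorm(200, sd = 0.4) > 0, "p", "n")
  errs <- vapply(c(1, 2, 5, 20, 100), function(ms) {
    m <- fit_tree(x, y, tree_config(max_splits = ms))
    expect_lte(tree_n_splits <- sum(m$fit$frame$var != "<leaf>"), ms)
    mean(predict_labels(predict_posterior(m, x)) != y)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("kNN posteriors are vote fractions with index tie-breaks", {
  x <- cn(c(0, 3), c(0, 4))
  y <- c("a", "b")
  m <- fit_knn(x, y, knn_config(k = 1))
  # query on a training point: posterior 1.0 for its label
  expect_equal(unname(predict_posterior(m, cn(0, 0))[1, ]), c(1, 0))
  # the (0,0)-(3,4) distance is 5 under the scaler-free geometry: a query
  # slightly nearer (3,4) goes to b
  m_raw <- fit_knn(cn(c(0, 3, 0, 3), c(0, 4, 4, 0)), c("a", "b", "a", "b"),
                   knn_config(k = 1))
  expect_identical(predict_labels(predict_posterior(m_raw, cn(2.9, 3.9))), "b")

  # equidistant neighbours: lower training index wins
  m2 <- fit_knn(cn(c(1, -1), c(0, 0)), c("a", "b"), knn_config(k = 1))
  expect_equal(unname(predict_posterior(m2, cn(0, 0))[1, ]), c(1, 0))

  # k = n: posterior equals the global class frequencies for any query
  set.seed(7)
  x3 <- cn(rnorm(10), rnorm(10))
  y3 <- c(rep("a", 7), rep("b", 3))
  m3 <- fit_knn(x3, y3, knn_config(k = 10))
  p <- predict_posterior(m3, cn(c(0, 100), c(0, -50)))
  expect_equal(unname(p), matrix(c(0.7, 0.7, 0.3, 0.3), 2))

  expect_error(fit_knn(x, y, knn_config(k = 3)), "exceeds")
})

test_that("kNN with k = 1 has zero training error on distinct points", {
  set.seed(8)
  x <- cn(rnorm(30), rnorm(30))
  y <- sample(c("a", "b", "c"), 30, replace = TRUE)
  m <- fit_knn(x, y, knn_config(k = 1))
  expect_identical(predict_labels(predict_posterior(m, x)), y)
})

test_that("committee averaging is the renormalized member mean", {
  p1 <- matrix(c(1, 0), 1, dimnames = list(NULL, c("a", "b")))
  p2 <- matrix(c(0, 1), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(unclass(committee_posterior(list(p1, p2)))[1, ]),
               c(0.5, 0.5))
  # idempotence on identical members
  expect_equal(unclass(committee_posterior(list(p1, p1, p1)))[1, ],
               p1[1, ])
  # three members equal the brute-force elementwise average
  set.seed(9)
  mk <- function() {
    m <- matrix(runif(12), 4)
    m <- m / rowSums(m)
    colnames(m) <- c("a", "b", "c")
    m
  }
  ms <- list(mk(), mk(), mk())
  avg <- (ms[[1]] + ms[[2]] + ms[[3]]) / 3
  expect_equal(unclass(committee_posterior(ms)), avg / rowSums(avg),
               ignore_attr = TRUE)
  # mismatched class lists are rejected
  p3 <- matrix(c(0, 1), 1, dimnames = list(NULL, c("a", "c")))
  expect_error(committee_posterior(list(p1, p3)), "mismatched")
})

test_that("all posteriors row-normalize to 1 and agree on unanimous argmax", {
  fx <- session_fixture(1L)
  com <- full_committee_fixture("binary")
  posts <- lapply(com$members, predict_posterior, x = fx$x[1:50, ])
  for (p in posts) {
    expect_true(all(p >= 0))
    expect_equal(unname(rowSums(p)), rep(1, 50), tolerance = 1e-9)
  }
  avg <- committee_posterior(posts)
  expect_equal(unname(rowSums(avg)), rep(1, 50), tolerance = 1e-9)
  labs <- vapply(posts, predict_labels, character(50))
  agree <- labs[, 1] == labs[, 2] & labs[, 2] == labs[, 3]
  expect_identical(predict_labels(avg)[agree], labs[agree, 1])
})

test_that("committee bundles round-trip through disk", {
  com <- full_committee_fixture("binary")
  fx <- session_fixture(1L)
  p <- withr::local_tempfile(fileext = ".rds")
  save_committee(com, p)
  back <- load_committee(p)
  expect_equal(predict_posterior(back, fx$x[1:10, ]),
               predict_posterior(com, fx$x[1:10, ]))
  saveRDS(list(format = "other"), p)
  expect_error(load_committee(p), "bundle")
})
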