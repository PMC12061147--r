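#' Node impurity measures
#'
#' `gini_impurity(p) = 1 - sum(p^2)`; `entropy_impurity(p) = -sum(p log2 p)`
#' (bits, with `0 log 0 = 0`). `p` is a vector of class proportions at a
#' node. A pure node has impurity 0 under both; a balanced two-class node
#' has Gini 0.5 and entropy 1 bit.
#'
#' @param p numeric vector of class proportions (non-negative, sums to 1).
#' @return scalar impurity.
#' @export
gini_impurity <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  1 - sum(p^2)
}

#' @rdname gini_impurity
#' @export
entropy_impurity <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-9)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Committee member configurations
#'
#' `tree_config()`: decision-tree settings -- at most `max_splits` internal
#' split nodes (default 100) and the split criterion (Gini's diversity index
#' by default, or entropy/information). `knn_config()`: neighbour count for
#' the Euclidean k-nearest-neighbour member (default 5).
#'
#' @param max_splits maximum number of internal splits, >= 1.
#' @param criterion `"gini"` or `"entropy"`.
#' @param min_leaf minimum samples per leaf.
#' @return a config list.
#' @export
tree_config <- function(max_splits = 100L, criterion = c("gini", "entropy"),
                        min_leaf = 1L) {
  if (!is_count(max_splits, 1L)) stopf("max_splits must be an integer >= 1")
  if (!is_count(min_leaf, 1L)) stopf("min_leaf must be an integer >= 1")
  list(max_splits = as.integer(max_splits),
       criterion = match.arg(criterion), min_leaf = as.integer(min_leaf))
}

#' @rdname tree_config
#' @param k neighbour count, >= 1 (validated against the training size at
#'   fit time).
#' @export
knn_config <- function(k = 5L) {
  if (!is_count(k, 1L)) stopf("k must be an integer >= 1")
  list(k = as.integer(k))
}

# ---- shared fit-time checks -------------------------------------------------

prepare_xy <- function(x, y, classes = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  if (nrow(x) != length(y)) stopf("x and y lengths differ")
  if (nrow(x) < 1L) stopf("training set is empty")
  if (is.null(classes)) classes <- sort(unique(y))
  classes <- as.character(classes)
  missing <- setdiff(classes, unique(y))
  if (length(missing) > 0L)
    stopf("class(es) absent from training data: %s", paste(missing, collapse = ", "))
  list(x = x, y = y, classes = classes)
}

# Train-set standardization (mean/sd per feature, sd 0 -> 1) used by the
# naive-Bayes and kNN members; trees see raw features.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd <= 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(scaler, x) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sd, "/")
}

check_features <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$features) ||
      (!is.null(colnames(x)) && !identical(colnames(x), model$features)))
    stopf("feature columns do not match the model's training features")
  storage.mode(x) <- "double"
  colnames(x) <- model$features
  x
}

new_posterior <- function(p, classes) {
  p <- matrix(p, ncol = length(classes), dimnames = list(NULL, classes))
  structure(p, class = c("class_posterior", "matrix"))
}

#' Predict per-sample class posteriors
#'
#' Generic over the three committee member models and the committee itself.
#' Every returned row is a probability vector over the model's classes
#' (non-negative, summing to 1).
#'
#' @param model a fitted model from [fit_naive_bayes()], [fit_tree()],
#'   [fit_knn()] or [fit_committee()].
#' @param x feature matrix (or data frame) with the training columns.
#' @param ... unused.
#' @return a `class_posterior`: samples x classes probability matrix.
#' @export
predict_posterior <- function(model, x, ...) UseMethod("predict_posterior")

#' Hard labels from a posterior
#'
#' Argmax per row; ties break toward the lower class index.
#'
#' @param posterior a `class_posterior` matrix.
#' @return character vector of class labels.
#' @export
predict_labels <- function(posterior) {
  colnames(posterior)[max.col(unclass(posterior), ties.method = "first")]
}

# ---- naive Bayes ------------------------------------------------------------

#' Gaussian naive Bayes committee member
#'
#' Posterior proportional to the class prior times the product of
#' per-feature Gaussian class-conditional likelihoods (feature independence
#' assumed), normalized across classes. Per-class means/variances are
#' maximum-likelihood estimates with variances floored at 1e-9; features are
#' standardized with train-set statistics before fitting.
#'
#' @param x feature matrix.
#' @param y class labels (coerced to character).
#' @param classes optional explicit class list; any listed class absent from
#'   `y` is an error.
#' @param priors optional named prior probabilities per class (default:
#'   empirical class frequencies).
#' @return a model of class `nb_model`.
#' @export
fit_naive_bayes <- function(x, y, classes = NULL, priors = NULL) {
  d <- prepare_xy(x, y, classes)
  scaler <- fit_scaler(d$x)
  xs <- apply_scaler(scaler, d$x)
  if (is.null(priors)) {
    priors <- table(factor(d$y, levels = d$classes)) / length(d$y)
    priors <- as.numeric(priors)
  } else {
    stopifnot(setequal(names(priors), d$classes))
    priors <- as.numeric(priors[d$classes]) / sum(priors)
  }
  p <- ncol(xs)
  mu <- t(matrix(vapply(d$classes, function(k)
    colMeans(xs[d$y == k, , drop = FALSE]), numeric(p)), nrow = p))
  va <- t(matrix(vapply(d$classes, function(k) {
    xk <- xs[d$y == k, , drop = FALSE]
    pmax(colMeans(xk^2) - colMeans(xk)^2, 1e-9) # ML variance, floored
  }, numeric(p)), nrow = p))
  structure(list(classes = d$classes, priors = priors, mu = mu, va = va,
                 scaler = scaler, features = colnames(d$x)),
            class = "nb_model")
}

#' @export
predict_posterior.nb_model <- function(model, x, ...) {
  x <- check_features(model, x)
  xs <- apply_scaler(model$scaler, x)
  ll <- vapply(seq_along(model$classes), function(k) {
    dens <- stats::dnorm(as.vector(xs),
                         rep(model$mu[k, ], each = nrow(xs)),
                         rep(sqrt(model$va[k, ]), each = nrow(xs)), log = TRUE)
    rowSums(matrix(dens, nrow = nrow(xs))) + log(model$priors[k])
  }, numeric(nrow(xs)))
  ll <- matrix(ll, ncol = length(model$classes))
  ll <- ll - apply(ll, 1, max)
  p <- exp(ll)
  new_posterior(p / rowSums(p), model$classes)
}

# ---- decision tree ----------------------------------------------------------

#' Decision-tree committee member
#'
#' Greedy recursive binary splits (via \pkg{rpart}) under the configured
#' criterion, grown fully and then pruned back along the cost-complexity
#' path to at most `max_splits` internal splits. Leaf posteriors are the
#' leaf class proportions. Trees use raw (unstandardized) features.
#'
#' @inheritParams fit_naive_bayes
#' @param cfg a [tree_config()].
#' @return a model of class `tree_model`.
#' @export
fit_tree <- function(x, y, cfg = tree_config(), classes = NULL) {
  d <- prepare_xy(x, y, classes)
  if (length(d$classes) == 1L) {
    return(structure(list(classes = d$classes, fit = NULL,
                          features = colnames(d$x)), class = "tree_model"))
  }
  df <- as.data.frame(d$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- factor(d$y, levels = d$classes)
  split <- if (cfg$criterion == "gini") "gini" else "information"
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      parms = list(split = split),
                      control = rpart::rpart.control(
                        minsplit = max(2L, 2L * cfg$min_leaf),
                        minbucket = cfg$min_leaf, cp = 0, xval = 0,
                        maxdepth = 30, maxcompete = 0, maxsurrogate = 0))
  ct <- fit$cptable
  ok <- ct[ct[, "nsplit"] <= cfg$max_splits, , drop = FALSE]
  if (nrow(ok) < nrow(ct)) fit <- rpart::prune(fit, cp = ok[nrow(ok), "CP"])
  structure(list(classes = d$classes, fit = fit, features = colnames(d$x)),
            class = "tree_model")
}

#' @export
predict_posterior.tree_model <- function(model, x, ...) {
  x <- check_features(model, x)
  if (is.null(model$fit)) # single-class training set
    return(new_posterior(rep(1, nrow(x)), model$classes))
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  p <- stats::predict(model$fit, newdata = df, type = "prob")
  stopifnot(identical(colnames(p), model$classes))
  new_posterior(p, model$classes)
}

# Number of internal split nodes of a fitted tree member (0 for a stump).
tree_n_splits <- function(model) {
  if (is.null(model$fit)) return(0L)
  sum(model$fit$frame$var != "<leaf>")
}

# ---- k nearest neighbours ---------------------------------------------------

#' k-nearest-neighbour committee member
#'
#' Posterior = class vote fractions among the `k` Euclidean-nearest training
#' points (on train-set-standardized features); exact distance ties break by
#' training index.
#'
#' @inheritParams fit_naive_bayes
#' @param cfg a [knn_config()]; `cfg$k` must not exceed the training size.
#' @return a model of class `knn_model`.
#' @export
fit_knn <- function(x, y, cfg = knn_config(), classes = NULL) {
  d <- prepare_xy(x, y, classes)
  if (cfg$k > nrow(d$x))
    stopf("k = %d exceeds training size %d", cfg$k, nrow(d$x))
  scaler <- fit_scaler(d$x)
  structure(list(classes = d$classes, k = cfg$k,
                 xs = apply_scaler(scaler, d$x), y = d$y, scaler = scaler,
                 features = colnames(d$x)),
            class = "knn_model")
}

#' @export
predict_posterior.knn_model <- function(model, x, ...) {
  x <- check_features(model, x)
  qs <- apply_scaler(model$scaler, x)
  tr <- model$xs
  cls <- model$classes
  p <- t(apply(qs, 1, function(q) {
    d2 <- rowSums(sweep(tr, 2, q)^2)
    nn <- order(d2)[seq_len(model$k)] # stable: ties by training index
    tabulate(match(model$y[nn], cls), length(cls)) / model$k
  }))
  new_posterior(p, cls)
}

# ---- committee --------------------------------------------------------------

#' Fit the three-member classifier committee
#'
#' Trains the naive-Bayes, decision-tree and kNN members on the same data.
#'
#' @inheritParams fit_naive_bayes
#' @param tree a [tree_config()].
#' @param knn a [knn_config()]; `k` is capped at the training size.
#' @return a model of class `committee` with a `members` list.
#' @export
fit_committee <- function(x, y, classes = NULL, tree = tree_config(),
                          knn = knn_config()) {
  d <- prepare_xy(x, y, classes)
  knn$k <- min(knn$k, nrow(d$x))
  structure(list(
    classes = d$classes,
    members = list(nb = fit_naive_bayes(d$x, d$y, d$classes),
                   tree = fit_tree(d$x, d$y, tree, d$classes),
                   knn = fit_knn(d$x, d$y, knn, d$classes)),
    features = colnames(d$x)), class = "committee")
}

#' @export
predict_posterior.committee <- function(model, x, ...) {
  committee_posterior(lapply(model$members, predict_posterior, x = x))
}

#' Average member posteriors into the committee posterior
#'
#' Unweighted arithmetic mean per class, renormalized per row. All members
#' must share the class list and sample count.
#'
#' @param members list of `class_posterior` matrices.
#' @return the averaged `class_posterior`.
#' @export
committee_posterior <- function(members) {
  stopifnot(length(members) >= 1L)
  cls <- colnames(members[[1]])
  n <- nrow(members[[1]])
  for (m in members) {
    if (!identical(colnames(m), cls))
      stopf("committee members have mismatched class lists")
    if (nrow(m) != n) stopf("committee members have mismatched sample counts")
  }
  avg <- Reduce(`+`, lapply(members, unclass)) / length(members)
  new_posterior(avg / rowSums(avg), cls)
}

#' Save / load a trained committee bundle
#'
#' Versioned on-disk bundle so a trained committee can be applied to new
#' sessions later (e.g. from the command line).
#'
#' @param committee a fitted `committee`.
#' @param path bundle file path.
#' @return `save_committee` returns `path` invisibly; `load_committee`
#'   returns the committee.
#' @export
save_committee <- function(committee, path) {
  stopifnot(inherits(committee, "committee"))
  saveRDS(list(format = "imupunch-committee", version = 1L,
               package_version = as.character(utils::packageVersion("imupunch")),
               committee = committee), path)
  invisible(path)
}

#' @rdname save_committee
#' @export
load_committee <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format, "imupunch-committee"))
    stopf("not an imupunch committee bundle: %s", path)
  b$committee
}
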