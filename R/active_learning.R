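#' Per-sample uncertainty as consensus entropy
#'
#' Shannon entropy (bits) of each posterior row,
#' `H(x) = sum_c P(c) log2(1 / P(c))` with `0 * log(1/0) = 0`. High entropy
#' marks windows on which the committee is most uncertain -- the prime
#' candidates for expert labeling. Always in `[0, log2(n_classes)]`.
#'
#' @param posterior a `class_posterior` matrix.
#' @return numeric vector of entropies in bits, one per sample.
#' @export
entropy_scores <- function(posterior) {
  p <- unclass(posterior)
  apply(p, 1, function(r) {
    r <- r[r > 0]
    -sum(r * log2(r))
  })
}

#' Pick the highest-uncertainty samples to query
#'
#' Returns the `batch` highest-scoring indices, in descending score order,
#' with exact ties broken by ascending index. Deterministic.
#'
#' @param scores numeric uncertainty scores over the pool.
#' @param batch number of queries; at most `length(scores)`.
#' @return integer vector of `batch` 1-based indices into `scores`.
#' @export
select_queries <- function(scores, batch) {
  if (length(scores) == 0L) stopf("empty pool: nothing to query")
  if (!is_count(batch, 1L) || batch > length(scores))
    stopf("batch must be an integer in [1, pool size]")
  ord <- order(-scores, seq_along(scores))
  ord[seq_len(batch)]
}

#' Label oracles
#'
#' `simulated_oracle(labels)` wraps hidden ground-truth labels: queried with
#' indices, it returns the true labels (the benchmarking oracle).
#' `interactive_oracle()` prompts a human expert per queried window, showing
#' the window's time span (and video frame range when a `sync_map` is
#' given), and accepts the label codes 0 no-punch / 1 jab / 2 hook /
#' 3 uppercut, re-prompting on anything else.
#'
#' @param labels full hidden label vector (simulated oracle).
#' @param windows optional [make_windows()] result for time spans.
#' @param sync optional [align_clocks()] result for frame ranges.
#' @param input function returning one line of user input (default
#'   `readline`); injectable for testing.
#' @param output function used to print prompts (default `cat`).
#' @return a function `f(indices) -> labels`.
#' @export
simulated_oracle <- function(labels) {
  force(labels)
  function(idx) labels[idx]
}

#' @rdname simulated_oracle
#' @export
interactive_oracle <- function(windows = NULL, sync = NULL,
                               input = function(prompt) readline(prompt),
                               output = cat) {
  codes <- c(`0` = "0", `1` = "1", `2` = "2", `3` = "3")
  function(idx) {
    vapply(idx, function(i) {
      span <- if (!is.null(windows))
        sprintf(" [%.2f s - %.2f s]", windows$start_s[i], windows$end_s[i]) else ""
      frames <- if (!is.null(windows) && !is.null(sync))
        sprintf(" [frames %d - %d]", time_to_frame(windows$start_s[i], sync),
                time_to_frame(windows$end_s[i], sync)) else ""
      output(sprintf("Window %d%s%s\n", i, span, frames))
      repeat {
        ans <- trimws(input("Label (0 no-punch / 1 jab / 2 hook / 3 uppercut): "))
        if (ans %in% codes) return(as.integer(ans))
        output("Invalid label code; enter 0, 1, 2 or 3.\n")
      }
    }, integer(1))
  }
}

#' Pool-based query-by-committee active learning
#'
#' Seeds the labeled set with a random `init_frac` of the pool (stratified
#' by `strata` when given), then iterates: fit the three-member committee on
#' the labeled set, score the remaining pool by consensus entropy of the
#' averaged committee posterior, query the `batch_frac` most uncertain
#' samples from the oracle, and add them to the labeled set -- until the
#' labeled fraction reaches `stop_frac`. The default schedule (5% initial,
#' 5% batches, stop at 15%) performs exactly three labeling stages.
#'
#' @param x pool feature matrix (or data frame of features only).
#' @param oracle a label provider `f(indices) -> labels` (see
#'   [simulated_oracle()]); an `NA` answer is treated as a refusal and
#'   aborts the loop with the partial state attached to the error condition.
#' @param init_frac,batch_frac,stop_frac fractions in `(0, 1]` with
#'   `init_frac <= stop_frac`.
#' @param seed integer seed controlling the initial draw (and the random
#'   strategy); the same seed reproduces the exact query sequence.
#' @param strata optional per-sample strata (e.g. hidden classes) for the
#'   stratified initial draw; plain uniform sampling when `NULL`.
#' @param tree,knn member configurations.
#' @param eval_x,eval_y optional held-out evaluation set; when given, each
#'   round's accuracy/precision/recall/F1 are recorded in the history.
#' @param strategy `"entropy"` (query by committee) or `"random"` (the
#'   random-sampling baseline at the same budget).
#' @return a list with `committee` (fit on the final labeled set) and
#'   `state`, an `al_state` list: `labeled`, `pool`, `queries` (per stage),
#'   `history` (one row per round), `seed`.
#' @export
qbc_loop <- function(x, oracle, init_frac = 0.05, batch_frac = 0.05,
                     stop_frac = 0.15, seed = 1L, strata = NULL,
                     tree = tree_config(), knn = knn_config(),
                     eval_x = NULL, eval_y = NULL,
                     strategy = c("entropy", "random")) {
  strategy <- match.arg(strategy)
  x <- as.matrix(x)
  n <- nrow(x)
  for (f in c(init_frac, batch_frac, stop_frac))
    if (!is_number(f) || f <= 0 || f > 1) stopf("fractions must be in (0, 1]")
  if (init_frac > stop_frac) stopf("init_frac must be <= stop_frac")
  if (n < 2L) stopf("pool too small")

  with_seed(seed, {
    n_init <- max(1L, ceiling(init_frac * n))
    if (!is.null(strata)) {
      stopifnot(length(strata) == n)
      idx0 <- unlist(lapply(split(seq_len(n), strata), function(ix) {
        sample(ix, max(1L, round(init_frac * length(ix))))
      }), use.names = FALSE)
    } else {
      idx0 <- sample.int(n, n_init)
    }
    labeled <- sort(idx0)
    queries <- list(labeled)
    ans <- oracle(labeled)
    if (anyNA(ans)) abort_al(labeled, setdiff(seq_len(n), labeled), queries,
                             NULL, seed, "oracle refused an initial query")
    ylab <- stats::setNames(rep(NA_character_, n), NULL)
    ylab[labeled] <- as.character(ans)

    history <- NULL
    round <- 0L
    committee <- NULL
    repeat {
      pool <- setdiff(seq_len(n), labeled)
      stopifnot(length(intersect(labeled, pool)) == 0L)
      committee <- fit_committee(x[labeled, , drop = FALSE], ylab[labeled],
                                 tree = tree, knn = knn)
      row <- data.frame(round = round, labeled_frac = length(labeled) / n,
                        n_labeled = length(labeled))
      if (!is.null(eval_x)) {
        post <- predict_posterior(committee, as.matrix(eval_x))
        rep_ <- summarize_confusion(confusion(as.character(eval_y),
                                              predict_labels(post),
                                              classes = union(committee$classes,
                                                              unique(as.character(eval_y)))))
        row$accuracy <- rep_$accuracy
        row$precision <- rep_$precision
        row$recall <- rep_$recall
        row$f1 <- rep_$f1
      }
      history <- rbind(history, row)
      if (length(labeled) / n >= stop_frac || length(pool) == 0L) break

      batch <- min(max(1L, ceiling(batch_frac * n)), length(pool))
      if (strategy == "entropy") {
        scores <- entropy_scores(predict_posterior(committee,
                                                   x[pool, , drop = FALSE]))
        q <- pool[select_queries(scores, batch)]
      } else {
        q <- sample(pool, batch)
      }
      ans <- oracle(q)
      if (anyNA(ans)) abort_al(labeled, pool, queries, history, seed,
                               "oracle refused a query")
      ylab[q] <- as.character(ans)
      labeled <- sort(c(labeled, q))
      queries <- c(queries, list(q))
      round <- round + 1L
    }
    state <- structure(list(labeled = labeled,
                            pool = setdiff(seq_len(n), labeled),
                            queries = queries, history = history, seed = seed),
                       class = "al_state")
    list(committee = committee, state = state)
  })
}

# Abort the loop, persisting the partial state on the error condition.
abort_al <- function(labeled, pool, queries, history, seed, msg) {
  state <- structure(list(labeled = labeled, pool = pool, queries = queries,
                          history = history, seed = seed), class = "al_state")
  stop(structure(class = c("qbc_aborted", "error", "condition"),
                 list(message = msg, call = NULL, state = state)))
}

#' Write an active-learning state ledger to JSON
#'
#' @param state an `al_state` from [qbc_loop()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_al_state <- function(state, path) {
  stopifnot(inherits(state, "al_state"))
  jsonlite::write_json(list(labeled = state$labeled, pool = state$pool,
                            queries = state$queries, history = state$history,
                            seed = state$seed),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
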