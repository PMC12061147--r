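#' Confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`.
#'
#' @param true,pred label vectors of equal length (coerced to character).
#' @param classes class list fixing row/column order; a label outside it is
#'   an error.
#' @return integer matrix, classes x classes.
#' @export
confusion <- function(true, pred, classes = NULL) {
  true <- as.character(true)
  pred <- as.character(pred)
  if (length(true) != length(pred)) stopf("true and pred lengths differ")
  if (is.null(classes)) classes <- sort(unique(c(true, pred)))
  classes <- as.character(classes)
  bad <- setdiff(unique(c(true, pred)), classes)
  if (length(bad) > 0L)
    stopf("label(s) outside the class list: %s", paste(bad, collapse = ", "))
  m <- table(factor(true, levels = classes), factor(pred, levels = classes))
  m <- unclass(m)
  dimnames(m) <- list(true = classes, predicted = classes)
  m
}

#' Summarize a confusion matrix into an evaluation report
#'
#' Accuracy = trace / total; per-class precision and recall with the 0/0 = 0
#' convention; macro-averaged precision and recall; F1 as the harmonic mean
#' of macro precision and macro recall.
#'
#' @param m confusion matrix from [confusion()].
#' @param task,hand,labeled_frac optional report tags.
#' @return an `eval_report` list: `confusion`, `accuracy`, `precision`,
#'   `recall`, `f1`, `per_class` (data frame), and the tags.
#' @export
summarize_confusion <- function(m, task = NA_character_, hand = NA_character_,
                                labeled_frac = NA_real_) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), sum(m) > 0)
  total <- sum(m)
  acc <- sum(diag(m)) / total
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec_c <- safe_div(diag(m), colSums(m))
  rec_c <- safe_div(diag(m), rowSums(m))
  f1_c <- safe_div(2 * prec_c * rec_c, prec_c + rec_c)
  prec <- mean(prec_c)
  rec <- mean(rec_c)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  structure(list(confusion = m, accuracy = acc, precision = prec,
                 recall = rec, f1 = f1,
                 per_class = data.frame(class = rownames(m),
                                        precision = unname(prec_c),
                                        recall = unname(rec_c),
                                        f1 = unname(f1_c)),
                 task = task, hand = hand, labeled_frac = labeled_frac),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report>%s%s%s\n",
              if (!is.na(x$task)) paste0(" task=", x$task) else "",
              if (!is.na(x$hand)) paste0(" hand=", x$hand) else "",
              if (!is.na(x$labeled_frac))
                sprintf(" labeled=%.0f%%", 100 * x$labeled_frac) else ""))
  print(x$confusion)
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Aggregate active-learning histories into a learning curve
#'
#' One row per round: the labeled fraction and the mean and standard
#' deviation of each evaluation metric across the supplied histories
#' (seeds). The metric columns mirror the accuracy/precision/recall/F1
#' reporting schema.
#'
#' @param histories list of `al_state` objects (or their `history` data
#'   frames) with evaluation metrics recorded.
#' @return data frame: `round`, `labeled_frac`, then `<metric>_mean` and
#'   `<metric>_sd` for accuracy, precision, recall, f1.
#' @export
learning_curve <- function(histories) {
  stopifnot(length(histories) >= 1L)
  hs <- lapply(histories, function(h) {
    if (inherits(h, "al_state")) h$history else as.data.frame(h)
  })
  metrics <- c("accuracy", "precision", "recall", "f1")
  stopifnot(all(vapply(hs, function(h) all(metrics %in% names(h)), logical(1))))
  rounds <- sort(unique(unlist(lapply(hs, `[[`, "round"))))
  do.call(rbind, lapply(rounds, function(r) {
    rows <- do.call(rbind, lapply(hs, function(h) h[h$round == r, ]))
    out <- data.frame(round = r, labeled_frac = mean(rows$labeled_frac))
    for (mname in metrics) {
      out[[paste0(mname, "_mean")]] <- mean(rows[[mname]])
      out[[paste0(mname, "_sd")]] <- if (nrow(rows) > 1L) stats::sd(rows[[mname]]) else 0
    }
    out
  }))
}
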