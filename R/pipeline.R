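#' Pipeline configuration
#'
#' All tunables of the detection pipeline in one validated tree, with
#' defaults matching the intended field conditions: 200 Hz streams, 180-sample
#' windows at stride 1, the 60% overlap labeling criterion, a 100-split
#' Gini tree and k = 5 neighbours in the committee, the 5% -> 15%
#' active-learning budget in 5% batches, and 0.8 s / 0.2 s smoothing
#' constraints. Unknown keys are rejected.
#'
#' @param ... overrides as `key = value` (nested lists for subtrees, e.g.
#'   `al = list(stop_frac = 0.2)`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    window_len = 180L,
    stride = 1L,
    criterion = 0.6,
    bands = c(0, 5, 15, 50),
    tree = list(max_splits = 100L, criterion = "gini", min_leaf = 1L),
    knn = list(k = 5L),
    al = list(init_frac = 0.05, batch_frac = 0.05, stop_frac = 0.15),
    smoothing = list(min_gap_s = 0.2, min_event_s = 0.2, avg_event_s = 0.8),
    video = list(fps = 60, v0_utc_s = NULL),
    anchor = "start",
    simulate = list(duration_s = 60, n_punches = 20L, fs = 200,
                    combo_prob = 0, min_gap_s = 0.5, noise_sd = 0.3,
                    hand = "lead")
  )
  structure(merge_config(defaults, list(...)), class = "pipeline_config")
}

merge_config <- function(defaults, overrides, path = "") {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L)
    stopf("unknown config key(s): %s", paste0(path, unknown, collapse = ", "))
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(overrides[[k]]),
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' Read a pipeline configuration from a YAML file
#'
#' File keys override the defaults; `overrides` (e.g. parsed command-line
#' flags) override the file.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  base <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, as.list(base))
  structure(merge_config(unclass(cfg), overrides), class = "pipeline_config")
}

# Features + labels for one session under a config.
session_features <- function(session, config) {
  windows <- make_windows(session$stream, config$window_len, config$stride)
  features <- extract_features(session$stream, windows, config$bands)
  labels <- label_windows(windows, session$events, config$criterion)
  list(windows = windows, features = features, labels = labels)
}

# Train binary + type committees on pool features via the QBC loop.
train_hierarchy <- function(pool, config, eval = NULL, strategy = "entropy") {
  x <- feature_columns(pool$features)
  tr <- do.call(tree_config, config$tree)
  kn <- do.call(knn_config, config$knn)
  al <- config$al
  # the binary loop is stratified by punch type (not just punch/no-punch):
  # a 5% init draw that misses one type entirely leaves the committee
  # confidently wrong on it, and entropy ranking then never queries it
  bin <- qbc_loop(x, simulated_oracle(pool$labels$y_bin),
                  init_frac = al$init_frac, batch_frac = al$batch_frac,
                  stop_frac = al$stop_frac, seed = config$seed,
                  strata = pool$labels$y_type, tree = tr, knn = kn,
                  eval_x = if (is.null(eval)) NULL else feature_columns(eval$features),
                  eval_y = if (is.null(eval)) NULL else eval$labels$y_bin,
                  strategy = strategy)
  # the classification stage is 3-class over punch windows only (the
  # recognition stage already gates out the no-punch background), so the
  # labeling budget concentrates on punches instead of background windows
  punch <- which(pool$labels$y_type > 0L)
  epunch <- if (is.null(eval)) integer(0) else which(eval$labels$y_type > 0L)
  typ <- qbc_loop(x[punch, , drop = FALSE],
                  simulated_oracle(pool$labels$y_type[punch]),
                  init_frac = al$init_frac, batch_frac = al$batch_frac,
                  stop_frac = al$stop_frac, seed = config$seed + 1L,
                  strata = pool$labels$y_type[punch], tree = tr, knn = kn,
                  eval_x = if (length(epunch) == 0L) NULL else
                    feature_columns(eval$features)[epunch, , drop = FALSE],
                  eval_y = if (length(epunch) == 0L) NULL else
                    eval$labels$y_type[epunch],
                  strategy = strategy)
  list(binary = bin, type = typ)
}

#' Detect punch events in a stream with trained committees
#'
#' Runs the hierarchical inference: per-window binary prediction, temporal
#' smoothing, event extraction, and mode-based type assignment.
#'
#' @param binary_committee,type_committee fitted committees for the
#'   punch/no-punch and type tasks.
#' @param stream an [imu_stream()].
#' @param config a [pipeline_config()].
#' @return list with `events` (typed data frame), `sequence` (smoothed
#'   [label_sequence()]), `windows`, `features`.
#' @export
detect_events <- function(binary_committee, type_committee, stream, config) {
  windows <- make_windows(stream, config$window_len, config$stride)
  features <- extract_features(stream, windows, config$bands)
  seq <- predict_sequence(binary_committee, features, windows)
  sm <- config$smoothing
  seq <- smooth_labels(seq, sm$min_gap_s, sm$min_event_s, sm$avg_event_s)
  events <- extract_events(seq, hand = stream$hand, anchor = config$anchor)
  if (nrow(events) > 0L && !is.null(type_committee)) {
    post <- predict_posterior(type_committee, feature_columns(features))
    events <- assign_types(events, post)
  }
  list(events = events, sequence = seq, windows = windows, features = features)
}

#' Run the full pipeline on one simulated (or supplied) session pair
#'
#' Simulate (or load) a training and a held-out session, extract features
#' and overlap labels, train the binary and type committees with the
#' query-by-committee loop against a simulated oracle, detect events on the
#' held-out session, build the cut list when a video clock is configured,
#' and evaluate window-level performance. All artifacts land in `out_dir`:
#' `events.json`, `cut_list.csv` (when a video clock is given),
#' `learning_curve.csv`, `report.csv`, the two model bundles, the
#' active-learning state JSONs, and `manifest.json` (config + seed +
#' package version), making a run reproducible from its manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed.
#' @param train_csv,test_csv optional IMU CSV paths with matching
#'   `events.json` files alongside; when `NULL`, sessions are simulated per
#'   `config$simulate` (seed and seed + 1000).
#' @return list with `detection`, `reports`, `curve`, `paths`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         train_csv = NULL, test_csv = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  load_session <- function(csv) {
    stream <- read_imu_csv(csv)
    events <- read_events_json(file.path(dirname(csv), "events.json"))
    list(stream = stream, events = events)
  }
  message("stage simulate/load: preparing sessions (seed ", config$seed, ")")
  if (is.null(train_csv)) {
    sim <- config$simulate
    mk <- function(seed) generate_session(synthetic_config(
      duration_s = sim$duration_s, n_punches = sim$n_punches, fs = sim$fs,
      combo_prob = sim$combo_prob, min_gap_s = sim$min_gap_s,
      noise_sd = sim$noise_sd, hand = sim$hand, seed = seed))
    train <- mk(config$seed)
    test <- mk(config$seed + 1000L)
  } else {
    train <- load_session(train_csv)
    test <- load_session(test_csv %||% train_csv)
  }

  message("stage features: extracting windows and features")
  pool <- session_features(train, config)
  held <- session_features(test, config)

  message("stage train-al: query-by-committee loops (binary, type)")
  models <- train_hierarchy(pool, config, eval = held)

  message("stage detect: hierarchical inference on the held-out session")
  det <- detect_events(models$binary$committee, models$type$committee,
                       test$stream, config)

  paths <- list(events = file.path(out_dir, "events.json"),
                curve = file.path(out_dir, "learning_curve.csv"),
                report = file.path(out_dir, "report.csv"),
                manifest = file.path(out_dir, "manifest.json"),
                model_binary = file.path(out_dir, "committee_binary.rds"),
                model_type = file.path(out_dir, "committee_type.rds"),
                al_binary = file.path(out_dir, "al_state_binary.json"),
                al_type = file.path(out_dir, "al_state_type.json"))
  write_events_json(det$events, paths$events)
  save_committee(models$binary$committee, paths$model_binary)
  save_committee(models$type$committee, paths$model_type)
  write_al_state(models$binary$state, paths$al_binary)
  write_al_state(models$type$state, paths$al_type)

  curve <- rbind(cbind(task = "recognition", learning_curve(list(models$binary$state))),
                 cbind(task = "classification", learning_curve(list(models$type$state))))
  utils::write.csv(curve, paths$curve, row.names = FALSE)

  message("stage evaluate: window-level reports on the held-out session")
  rep_bin <- summarize_confusion(
    confusion(held$labels$y_bin,
              predict_labels(predict_posterior(models$binary$committee,
                                               feature_columns(held$features))),
              classes = c("0", "1")),
    task = "recognition", hand = test$stream$hand,
    labeled_frac = utils::tail(models$binary$state$history$labeled_frac, 1))
  hp <- which(held$labels$y_type > 0L) # classification: punch windows only
  rep_typ <- summarize_confusion(
    confusion(held$labels$y_type[hp],
              predict_labels(predict_posterior(
                models$type$committee,
                feature_columns(held$features)[hp, , drop = FALSE])),
              classes = as.character(1:3)),
    task = "classification", hand = test$stream$hand,
    labeled_frac = utils::tail(models$type$state$history$labeled_frac, 1))
  report <- data.frame(task = c(rep_bin$task, rep_typ$task),
                       hand = c(rep_bin$hand, rep_typ$hand),
                       labeled_frac = c(rep_bin$labeled_frac, rep_typ$labeled_frac),
                       accuracy = c(rep_bin$accuracy, rep_typ$accuracy),
                       precision = c(rep_bin$precision, rep_typ$precision),
                       recall = c(rep_bin$recall, rep_typ$recall),
                       f1 = c(rep_bin$f1, rep_typ$f1))
  utils::write.csv(report, paths$report, row.names = FALSE)

  if (!is.null(config$video$v0_utc_s)) {
    message("stage segment-video: building the cut list")
    sync <- align_clocks(test$stream,
                         video_clock(config$video$v0_utc_s, config$video$fps))
    cuts <- segment_video(det$events, sync)
    paths$cut_list <- file.path(out_dir, "cut_list.csv")
    write_cut_list(cuts, paths$cut_list)
  }

  manifest <- list(package = "imupunch",
                   version = as.character(utils::packageVersion("imupunch")),
                   seed = config$seed,
                   config = unclass(config))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(detection = det, reports = list(binary = rep_bin, type = rep_typ),
                 curve = curve, models = models, paths = paths,
                 truth = test$events))
}
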