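#' End-to-end run configuration
#'
#' Bundles the simulation, labeling, model and evaluation settings of
#' one experiment; every stochastic component derives its stream from
#' the single `seed`.
#'
#' @param sim a `sim_config`.
#' @param paradigm a `paradigm_spec` (or preset name) for LSTM
#'   training and evaluation.
#' @param lstm an `lstm_config` sized to the paradigm.
#' @param classifier a `classifier_config` sized to the paradigm.
#' @param segment_duration segment length in seconds (10 at paper
#'   scale; 2 for the desk preset so a 100-Hz segment still spans 200
#'   time steps).
#' @param train_fraction fraction of lead seizures in training.
#' @param exclusion_days,postictal_minutes,lead_gap_minutes exclusion
#'   windows (defaults 100 d / 4 h / 4 h; desk runs scale them down).
#' @param out_dir run directory for artifacts.
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(sim, paradigm, lstm = NULL, classifier = NULL,
                       segment_duration = 10, train_fraction = 0.8,
                       exclusion_days = 100, postictal_minutes = 240,
                       lead_gap_minutes = 240, out_dir = tempfile("run_"),
                       seed = 1) {
  if (is.character(paradigm)) paradigm <- paradigm_preset(paradigm)
  if (is.null(lstm))
    lstm <- lstm_config(n_labels = paradigm$n_labels, seed = seed)
  if (is.null(classifier))
    classifier <- classifier_config(paradigm$n_labels, seed = seed)
  stopifnot(lstm$n_labels == paradigm$n_labels,
            classifier$n_labels == paradigm$n_labels)
  structure(list(sim = sim, paradigm = paradigm, lstm = lstm,
                 classifier = classifier,
                 segment_duration = segment_duration,
                 train_fraction = train_fraction,
                 exclusion_days = exclusion_days,
                 postictal_minutes = postictal_minutes,
                 lead_gap_minutes = lead_gap_minutes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Desk-scale run preset
#'
#' 4 channels at 100 Hz with 2-s segments and the reduced LSTM; the
#' exclusion windows are scaled to the short synthetic recording
#' (no initial exclusion, 1-h post-ictal window, 2-h lead gap).
#'
#' @param paradigm preset name or `paradigm_spec`.
#' @param duration_days simulated days.
#' @param seed master seed.
#' @param sim_args list of extra [sim_config()] overrides.
#' @param ... overrides passed to [run_config()].
#' @export
run_config_desk <- function(paradigm = "paradigm1", duration_days = 2,
                            seed = 1, sim_args = list(), ...) {
  if (is.character(paradigm)) paradigm <- paradigm_preset(paradigm)
  sa <- list(duration_days = duration_days, seed = seed)
  sa[names(sim_args)] <- sim_args
  sim <- do.call(sim_config_desk, sa)
  args <- list(sim = sim, paradigm = paradigm,
               lstm = lstm_config_desk(paradigm$n_labels, seed = seed),
               classifier = classifier_config(paradigm$n_labels, seed = seed,
                                              learning_rate = 1e-3),
               segment_duration = 2, exclusion_days = 0,
               postictal_minutes = 60, lead_gap_minutes = 120, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(run_config, args)
}

# Normalize a stored recording day by day with the rolling-window
# divisor; returns an in-memory environment of normalized minutes (for
# desk-scale ranges) plus the screen/usable bookkeeping.
normalize_recording <- function(manifest, state_days = 30) {
  nch <- manifest$channels
  state <- normalization_state(nch, state_days)
  minutes <- manifest$records$start_minute
  days <- sort(unique(minutes %/% 1440))
  norm <- new.env(parent = emptyenv())
  kept <- integer(0); dropped <- integer(0)
  for (d in days) {
    day_min <- minutes[minutes %/% 1440 == d]
    recs <- read_minutes(manifest, min(day_min), max(day_min) + 1L)$records
    for (r in recs) {
      if (!isTRUE(c(screen_minute(r)))) {
        dropped <- c(dropped, r$start_minute)
        next
      }
      nr <- normalize_minute(r, state)
      if (!isTRUE(attr(nr, "usable"))) {
        dropped <- c(dropped, r$start_minute)
        next
      }
      assign(as.character(nr$start_minute), nr, envir = norm)
      kept <- c(kept, r$start_minute)
    }
    state <- update_normalization(state, recs)
  }
  list(fetch = function(m) get(as.character(m), envir = norm),
       kept = sort(kept), dropped = sort(dropped), state = state)
}

#' Run the full pipeline: simulate, build, train, fuse, evaluate
#'
#' Stages: draw a seizure schedule and simulate the recording into an
#' on-disk minute store; normalize and screen; flag lead seizures,
#' apply exclusions and split by seizures; build the balanced LSTM
#' training set and train the stacked LSTM; cache per-minute LSTM
#' outputs; train the fusion classifier; evaluate on the unbalanced
#' test minutes (ROC/AUC with Hanley-McNeil interval for two-label
#' paradigms, confusion matrix plus time-matched baseline otherwise).
#' Artifacts (manifest, catalog, dataset tables, cached outputs,
#' evaluation JSON) are written under `config$out_dir`.
#'
#' @param config a `run_config`.
#' @param verbose print stage progress.
#' @return an object of class `pipeline_result`: `catalog`, `split`,
#'   `lstm_model`, `classifier`, `cached` (train+test LSTM outputs),
#'   `evaluation`, `run_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  say("stage simulate")
  schedule <- stage("simulate", generate_seizure_times(config$sim))
  store_dir <- file.path(config$out_dir, "store")
  manifest <- stage("simulate", write_recording(
    function(emit) simulate_recording(config$sim, schedule, sink = emit),
    store_dir))
  catalog <- find_lead_seizures(schedule, config$lead_gap_minutes)
  write_seizure_catalog(catalog, file.path(config$out_dir, "catalog.csv"))

  say("stage normalize")
  norm <- stage("normalize", normalize_recording(manifest))
  write_normalization_state(norm$state,
                            file.path(config$out_dir, "normalization.csv"))

  say("stage build-dataset")
  split <- stage("build-dataset",
                 split_by_seizures(catalog, config$train_fraction))
  eligible <- apply_exclusions(norm$kept, catalog,
                               exclusion_days = config$exclusion_days,
                               postictal_minutes = config$postictal_minutes)
  lab <- label_minutes(eligible, catalog, config$paradigm)
  labeled <- data.frame(minute = eligible, label = lab)
  labeled <- labeled[!is.na(labeled$label), ]
  train_lab <- labeled[labeled$minute < split$boundary_minute, ]
  test_lab <- labeled[labeled$minute >= split$boundary_minute, ]
  if (nrow(train_lab) == 0 || nrow(test_lab) == 0)
    stop("stage 'build-dataset' failed: empty train or test minute set")
  utils::write.csv(cbind(train_lab, split = "train"),
                   file.path(config$out_dir, "train_minutes.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(test_lab, split = "test"),
                   file.path(config$out_dir, "test_minutes.csv"),
                   row.names = FALSE)
  missing_label <- setdiff(0:(config$paradigm$n_labels - 1), train_lab$label)
  if (length(missing_label))
    stop(sprintf("stage 'build-dataset' failed: label %s has zero training minutes",
                 paste(missing_label, collapse = ",")))

  say("stage train-lstm")
  train_set <- stage("train-lstm", build_lstm_train_set(
    train_lab, norm$fetch, duration = config$segment_duration,
    seed = config$seed))
  model <- build_lstm_model(
    config$lstm,
    input_shape = c(dim(train_set$x)[3], dim(train_set$x)[2]))
  model <- stage("train-lstm",
                 train_lstm(model, train_set$x, train_set$labels,
                            verbose = verbose))

  say("stage cache-outputs")
  cached_train <- stage("cache-outputs", cache_lstm_outputs(
    model, train_lab$minute, norm$fetch, config$segment_duration))
  cached_test <- stage("cache-outputs", cache_lstm_outputs(
    model, test_lab$minute, norm$fetch, config$segment_duration))
  utils::write.csv(
    data.frame(minute = c(cached_train$minutes, cached_test$minutes),
               rbind(cached_train$lstm_out, cached_test$lstm_out)),
    file.path(config$out_dir, "lstm_outputs.csv"), row.names = FALSE)

  say("stage train-classifier")
  xin <- classifier_inputs(cached_train, catalog)
  bal <- build_classifier_train_set(xin, train_lab$label,
                                    seed = config$seed)
  clf <- build_classifier(config$classifier, ncol(xin))
  clf <- stage("train-classifier", train_classifier(clf, bal$x, bal$labels))

  say("stage evaluate")
  ev <- stage("evaluate", evaluate_predictions(
    clf, cached_test, test_lab$label, catalog, config$paradigm))
  jsonlite::write_json(ev$summary,
                       file.path(config$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(catalog = catalog, split = split, lstm_model = model,
                 classifier = clf,
                 cached = list(train = cached_train, test = cached_test),
                 train_minutes = train_lab, test_minutes = test_lab,
                 evaluation = ev, run_dir = config$out_dir,
                 config = config),
            class = "pipeline_result")
}

#' Evaluate a trained classifier on cached test minutes
#'
#' @param clf a trained `fusion_classifier`.
#' @param cached_test cached LSTM outputs of the test minutes.
#' @param labels true labels of those minutes.
#' @param catalog the `seizure_catalog`.
#' @param paradigm the labeling `paradigm_spec`.
#' @return list with `scores`, `summary`, and either `roc`+`ci`
#'   (two-label) or `confusion` (multi-label).
#' @export
evaluate_predictions <- function(clf, cached_test, labels, catalog,
                                 paradigm) {
  xin <- classifier_inputs(cached_test, catalog)
  scores <- predict_classifier(clf, xin)
  if (paradigm$n_labels == 2) {
    s <- combine_scores(scores[, 1], scores[, 2])
    roc <- roc_auc(s, labels == 0)
    ci <- hanley_mcneil_ci(roc$auc, roc$n_pos, roc$n_neg)
    list(scores = scores, roc = roc, ci = ci,
         summary = list(auc = roc$auc, ci_half_width = ci$half_width,
                        ci_lower = ci$lower, ci_upper = ci$upper,
                        n_pos = roc$n_pos, n_neg = roc$n_neg,
                        significant_vs_random = vs_random(ci)))
  } else {
    pred <- max.col(scores, ties.method = "first") - 1L
    cm <- confusion_and_baseline(pred, labels, paradigm$n_labels)
    list(scores = scores, confusion = cm,
         summary = list(accuracy = cm$accuracy,
                        selection = as.numeric(cm$selection),
                        sensitivity = as.numeric(cm$sensitivity),
                        n = cm$n))
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run (%s, %d labels)\n", x$config$paradigm$name,
              x$config$paradigm$n_labels))
  print(x$split)
  if (!is.null(x$evaluation$ci)) print(x$evaluation$ci)
  if (!is.null(x$evaluation$confusion)) print(x$evaluation$confusion)
  invisible(x)
}
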