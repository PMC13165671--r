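# End-to-end orchestration: simulate -> split -> scale -> window -> augment
# -> train -> calibrate -> evaluate -> explain, with multi-seed and ablation
# support.

ABLATION_SWITCHES <- c("disable_diversity", "disable_sparsity",
                       "disable_stability", "disable_stochastic_depth",
                       "disable_temperature")

#' Experiment configuration
#'
#' Bundles the data source (a synthetic [cohort_config()] or a directory of
#' recordings plus manifest), the split fractions and seed list, the model,
#' optimiser and augmentation configurations, evaluation options and
#' ablation switches.
#'
#' @param cohort A [cohort_config()] (synthetic source); ignored when
#'   `data_dir` is given.
#' @param data_dir Optional directory of recordings with `manifest.csv`.
#' @param fractions Train/val/test subject fractions.
#' @param senn A [senn_config()].
#' @param optimizer An [optimizer_spec()].
#' @param augmentation An [augmentation_config()].
#' @param seeds Seed list for multi-seed runs (the study uses
#'   `c(42, 123, 256, 789, 2024)`).
#' @param window,stride Windowing parameters.
#' @param ece_bins,threshold_step Evaluation options.
#' @param ablate Character vector of switches among
#'   `disable_diversity`, `disable_sparsity`, `disable_stability`,
#'   `disable_stochastic_depth`, `disable_temperature`.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(), data_dir = NULL,
                              fractions = c(0.70, 0.15, 0.15),
                              senn = senn_config(),
                              optimizer = optimizer_spec(),
                              augmentation = augmentation_config(),
                              seeds = c(42L, 123L, 256L, 789L, 2024L),
                              window = 128L, stride = 64L,
                              ece_bins = 10L, threshold_step = 0.01,
                              ablate = character(0)) {
  stopifnot(length(seeds) >= 1L, !anyDuplicated(seeds))
  bad <- setdiff(ablate, ABLATION_SWITCHES)
  if (length(bad) > 0L) {
    stop("unknown ablation switch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg <- structure(list(cohort = cohort, data_dir = data_dir,
                        fractions = fractions, senn = senn,
                        optimizer = optimizer, augmentation = augmentation,
                        seeds = as.integer(seeds),
                        window = as.integer(window),
                        stride = as.integer(stride),
                        ece_bins = as.integer(ece_bins),
                        threshold_step = threshold_step, ablate = ablate),
                   class = "experiment_config")
  apply_ablation(cfg)
}

# translate ablation switches into concrete configuration changes
apply_ablation <- function(config) {
  ab <- config$ablate
  if ("disable_diversity" %in% ab) config$senn$lambda_div <- 0
  if ("disable_sparsity" %in% ab) config$senn$lambda_spar <- 0
  if ("disable_stability" %in% ab) config$senn$lambda_stab <- 0
  if ("disable_stochastic_depth" %in% ab) config$senn$p_L <- 0
  config
}

load_cohort <- function(config) {
  if (!is.null(config$data_dir)) {
    read_cohort(config$data_dir)
  } else {
    generate_cohort(config$cohort)
  }
}

#' Run the full experiment for one seed
#'
#' Executes the pipeline with its leakage guards: the channel scaler and the
#' augmentation are fitted/applied on the training partition only; the
#' temperature and decision threshold are fitted on validation subjects; all
#' reported metrics come from test subjects. The seed drives the subject
#' split, initialisation, dropout, stochastic depth and augmentation; the
#' synthetic cohort itself is fixed by its own config seed (the data are the
#' same across run seeds, as with a recorded dataset).
#'
#' @param config An [experiment_config()].
#' @param seed Integer run seed.
#' @param cohort Optional pre-loaded `grf_cohort` (to avoid re-reading).
#' @param verbose Print per-epoch progress.
#' @return A `senn_run`: model, temperature scaler, operating point, subject
#'   and window metric tibbles, confusion matrices at 0.5 and tau*,
#'   reliability table, concept report, split, seed.
#' @export
run_experiment <- function(config, seed, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(cohort)) cohort <- load_cohort(config)
  split <- stratified_subject_split(cohort$manifest, config$fractions, seed)

  recs <- cohort$recordings
  ids <- vapply(recs, `[[`, "", "subject_id")
  train_ids <- split$subject_id[split$partition == "train"]
  scaler <- fit_channel_scaler(recs[ids %in% train_ids])
  zrecs <- apply_scaler(recs, scaler)

  train <- segment_partition(zrecs, split, "train", config$window, config$stride)
  val <- segment_partition(zrecs, split, "val", config$window, config$stride)
  test <- segment_partition(zrecs, split, "test", config$window, config$stride)
  assert_disjoint_subjects(train, val, test)
  raw_test <- segment_partition(recs, split, "test", config$window, config$stride)

  train_aug <- build_training_set(train, config$augmentation, seed = seed)
  model <- train_senn(train_aug, val, config$senn, config$optimizer,
                      seed = seed, verbose = verbose)
  eval <- evaluate_run(model, val, test, config = config,
                       raw_test_windows = raw_test$windows)
  structure(c(list(model = model, split = split, scaler = scaler,
                   seed = seed, config = config), eval),
            class = "senn_run")
}

#' Calibrate and evaluate a trained model
#'
#' Fits the temperature and decision threshold on the validation partition
#' (unless `disable_temperature`), pools calibrated window probabilities to
#' subjects and computes the metric suite on the test partition. Exposed
#' separately so ablations of the post-training stage reuse one fitted
#' model.
#'
#' @param model A `senn_model`.
#' @param val,test Validation and test `window_batch`es.
#' @param config The [experiment_config()].
#' @param raw_test_windows Optional raw (unstandardised) test windows for
#'   the sensor-correlation analysis.
#' @param disable_temperature Fix `T = 1` instead of fitting.
#' @return List with `temperature`, `operating_point`, `metrics` (one-row
#'   subject-level tibble), `window_metrics`, `confusion_05`,
#'   `confusion_tau`, `reliability`, `subject_probs`, `subject_labels`,
#'   `concepts`.
#' @export
evaluate_run <- function(model, val, test, config,
                         raw_test_windows = NULL,
                         disable_temperature = "disable_temperature" %in%
                           config$ablate) {
  ev_val <- senn_evaluate(model, val)
  scaler <- if (disable_temperature) {
    structure(list(T = 1, fit_nll = NA_real_, nll_at_unit = NA_real_),
              class = "temperature_scaler")
  } else {
    fit_temperature(ev_val$y_hat, val$labels)
  }
  val_cal <- apply_temperature(ev_val$y_hat, scaler$T)
  val_sp <- pool_subject_probabilities(val_cal, val$subject_ids)
  val_sl <- subject_labels(val)
  op <- select_threshold(val_sp, val_sl[names(val_sp)],
                         config$threshold_step)

  ev_test <- senn_evaluate(model, test)
  test_cal <- apply_temperature(ev_test$y_hat, scaler$T)
  test_sp <- pool_subject_probabilities(test_cal, test$subject_ids)
  test_sl <- subject_labels(test)[names(test_sp)]

  conf05 <- confusion_at(test_sp, test_sl, 0.5)
  conft <- confusion_at(test_sp, test_sl, op$tau)
  subj_prob <- probabilistic_metrics(test_sl, test_sp, config$ece_bins)
  win_prob <- probabilistic_metrics(test$labels, test_cal, config$ece_bins)
  rel <- expected_calibration_error(test$labels, test_cal, config$ece_bins)

  metrics <- dplyr::bind_cols(
    classification_metrics(conft["tp"], conft["fn"], conft["fp"], conft["tn"])[
      , 1:5],
    tibble::tibble(roc_auc = subj_prob$roc_auc,
                   avg_precision = subj_prob$avg_precision,
                   brier = win_prob$brier, ece = win_prob$ece,
                   tau = op$tau, temperature = scaler$T))

  concepts <- concept_report(ev_test, test$labels,
                             raw_windows = raw_test_windows,
                             subject_ids = test$subject_ids)

  list(temperature = scaler, operating_point = op, metrics = metrics,
       window_metrics = win_prob,
       confusion_05 = conf05, confusion_tau = conft,
       reliability = rel$table, subject_probs = test_sp,
       subject_labels = test_sl, concepts = concepts)
}

subject_labels <- function(batch) {
  keep <- !duplicated(batch$subject_ids)
  stats::setNames(batch$labels[keep], batch$subject_ids[keep])
}

#' @export
print.senn_run <- function(x, ...) {
  cat(sprintf("<senn_run> seed %d: subject AUC %.3f, sens %.3f, spec %.3f at tau*=%.2f (T=%.3f)\n",
              x$seed, x$metrics$roc_auc, x$metrics$sensitivity,
              x$metrics$specificity, x$metrics$tau, x$metrics$temperature))
  invisible(x)
}

#' Run the experiment over several seeds
#'
#' Maps [run_experiment()] over `config$seeds` and summarises every metric
#' across seeds with the t-distribution confidence interval (critical value
#' 2.776 for five seeds). A failed seed aborts the summary.
#'
#' @param config An [experiment_config()] (>= 2 seeds).
#' @param cohort Optional pre-loaded cohort.
#' @param verbose Print progress.
#' @return List with `per_seed` (tibble of per-seed metric rows), `summary`
#'   (tibble from [summarise_seeds()]), `runs` (list of `senn_run`).
#' @export
run_multi_seed <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(length(config$seeds) >= 2L)
  if (is.null(cohort)) cohort <- load_cohort(config)
  runs <- lapply(config$seeds, function(s) {
    if (verbose) message("seed ", s)
    run_experiment(config, s, cohort = cohort, verbose = FALSE)
  })
  per_seed <- dplyr::bind_rows(lapply(runs, function(r) {
    dplyr::mutate(r$metrics, seed = r$seed, .before = 1L)
  }))
  list(per_seed = per_seed, summary = summarise_seeds(per_seed),
       runs = runs)
}

#' Write a run's artifact bundle
#'
#' Training history and reliability table as CSV, metrics as JSON, concept
#' statistics and per-window explanations as CSV, the sensor-correlation
#' matrix as CSV.
#'
#' @param run A `senn_run`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run_bundle <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(run$reliability, file.path(dir, "reliability.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(as.list(run$metrics),
      list(confusion_05 = as.list(run$confusion_05),
           confusion_tau = as.list(run$confusion_tau), seed = run$seed)),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(run$concepts$stats, file.path(dir, "concepts.csv"),
                   row.names = FALSE)
  utils::write.csv(run$concepts$explanations,
                   file.path(dir, "explanations.csv"), row.names = FALSE)
  if (!is.null(run$concepts$sensor_corr)) {
    utils::write.csv(run$concepts$sensor_corr,
                     file.path(dir, "sensor_correlation.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
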