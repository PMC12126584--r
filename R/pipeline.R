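#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: the cohort to simulate, the
#' symptom and windowing, the model roster and the number of repeated
#' training runs. Repetition `i` of model `m` uses seed
#' `base_seed + i` combined with a per-model offset, recorded in the result
#' manifest.
#'
#' @param cohort A [cohort_config()].
#' @param symptom `"tremor"`, `"bradykinesia"` or `"dyskinesia"`.
#' @param window_length_s,overlap_frac Windowing parameters.
#' @param models Character subset of `c("rocket", "inception_default",
#'   "inception_tuned", "wavelet_mlp")`.
#' @param n_repetitions Training repetitions per model; 10 in the reference
#'   protocol.
#' @param base_seed Base seed for the repetition/model seed policy.
#' @param rocket_kernels,inception,inception_tuned,mlp Per-model settings for
#'   desk-scale runs: kernel count, [inception_config()]s and [mlp_config()].
#' @param train_frac Fraction of patients used for training (the rest form
#'   the held-out test set).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              symptom = "bradykinesia",
                              window_length_s = 30, overlap_frac = 0.5,
                              models = c("rocket", "wavelet_mlp"),
                              n_repetitions = 10, base_seed = 1L,
                              rocket_kernels = 10000,
                              inception = inception_config(),
                              inception_tuned = NULL,
                              mlp = mlp_config(),
                              train_frac = 0.8) {
  roster <- c("rocket", "inception_default", "inception_tuned", "wavelet_mlp")
  stopifnot(all(models %in% roster), n_repetitions >= 1)
  structure(list(cohort = cohort, symptom = symptom,
                 window_length_s = window_length_s,
                 overlap_frac = overlap_frac, models = models,
                 n_repetitions = as.integer(n_repetitions),
                 base_seed = as.integer(base_seed),
                 rocket_kernels = rocket_kernels, inception = inception,
                 inception_tuned = inception_tuned, mlp = mlp,
                 train_frac = train_frac),
            class = "experiment_config")
}

model_offset <- function(model) {
  match(model, c("rocket", "inception_default", "inception_tuned",
                 "wavelet_mlp")) * 1000L
}

train_one_model <- function(model, train_ds, config, seed) {
  switch(model,
    rocket = rocket_train(train_ds, n_kernels = config$rocket_kernels,
                          seed = seed),
    inception_default = {
      cfg <- config$inception
      cfg$n_classes <- length(train_ds$class_names)
      cfg$n_channels <- dim(train_ds$X)[2]
      cfg$seed <- seed
      inception_train(build_network(cfg), train_ds)
    },
    inception_tuned = {
      cfg <- config$inception_tuned %||% config$inception
      cfg$n_classes <- length(train_ds$class_names)
      cfg$n_channels <- dim(train_ds$X)[2]
      cfg$seed <- seed
      inception_train(build_network(cfg), train_ds)
    },
    wavelet_mlp = {
      cfg <- config$mlp
      cfg$seed <- seed
      wavelet_mlp_train(train_ds, cfg)
    },
    stop("unknown model: ", model))
}

#' Run the full estimation experiment on a synthetic cohort
#'
#' Simulates the cohort, cleans annotations, windows the recordings for the
#' configured symptom (merging tremor severities 3 and 4), splits patients
#' into train and test sets (grouped, stratified), trains each roster model
#' `n_repetitions` times with distinct seeds, evaluates every run on the
#' held-out patients, compares models by almost stochastic order when at
#' least two are present, and tabulates task-level misclassification counts
#' pooled across repetitions.
#'
#' @param config An [experiment_config()].
#' @param verbose Log one line per stage.
#' @return Object of class `experiment_result`: list with `reports` (per
#'   model, per repetition metric reports), `run_scores` (long data frame),
#'   `comparison` (ASO table or NULL), `error_table` (observed/expected/
#'   flagged), `manifest` (seeds and stage log).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  log_line <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(base_seed = config$base_seed, seeds = list(), stages = c())
  stage <- function(nm) {
    manifest$stages <<- c(manifest$stages, nm)
    log_line("stage: %s", nm)
  }

  stage("simulate")
  cohort <- generate_cohort(config$cohort)
  stage("clean")
  cohort <- clean_annotations(cohort)$recordings
  stage("window")
  ds <- windowed_dataset(cohort, config$symptom,
                         window_length_s = config$window_length_s,
                         overlap_frac = config$overlap_frac)
  if (config$symptom == "tremor") ds <- merge_tremor_classes(ds)

  stage("split")
  split <- grouped_stratified_holdout(
    cohort, fractions = c(train = config$train_frac,
                          test = 1 - config$train_frac),
    symptom = config$symptom, seed = config$base_seed)
  train_ds <- subset_windows(ds, which(ds$patient_id %in% split$train))
  test_ds <- subset_windows(ds, which(ds$patient_id %in% split$test))
  if (length(unique(train_ds$label)) < 2 || length(unique(test_ds$label)) < 2) {
    stop("degenerate split: a partition has fewer than two classes; ",
         "increase the cohort size or adjust prevalence")
  }

  reports <- list()
  run_scores <- data.frame()
  predictions <- list()
  ordinal <- config$symptom == "tremor"
  for (model in config$models) {
    reports[[model]] <- vector("list", config$n_repetitions)
    predictions[[model]] <- vector("list", config$n_repetitions)
    for (rep_i in seq_len(config$n_repetitions)) {
      seed <- config$base_seed + rep_i + model_offset(model)
      manifest$seeds[[paste(model, rep_i, sep = "_")]] <- seed
      stage(sprintf("train %s run %d", model, rep_i))
      res <- tryCatch({
        fitted <- train_one_model(model, train_ds, config, seed)
        pred <- predict(fitted, test_ds)
        list(pred = pred, report = metric_report(pred, ordinal = ordinal))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        manifest$stages <- c(manifest$stages,
                             sprintf("FAILED %s run %d: %s", model, rep_i,
                                     conditionMessage(res)))
        next
      }
      reports[[model]][[rep_i]] <- res$report
      predictions[[model]][[rep_i]] <- res$pred
      run_scores <- rbind(run_scores, data.frame(
        model = model, run = rep_i,
        balanced_accuracy = res$report$balanced_accuracy,
        map = res$report$map, stringsAsFactors = FALSE))
    }
  }

  comparison <- NULL
  ok_models <- unique(run_scores$model)
  if (length(ok_models) >= 2 && config$n_repetitions >= 2) {
    stage("compare")
    by_model <- split(run_scores$map, run_scores$model)
    comparison <- compare_models(by_model, metric = "map",
                                 seed = config$base_seed)
  } else {
    stage("compare skipped: fewer than two models with repeated runs")
  }

  stage("error analysis")
  error_table <- NULL
  first_model <- ok_models[1]
  preds <- Filter(Negate(is.null), predictions[[first_model]])
  if (length(preds) > 0) {
    task <- rep(test_ds$task, length(preds))
    yp <- unlist(lapply(preds, `[[`, "y_pred"))
    yt <- unlist(lapply(preds, `[[`, "y_true"))
    if (ordinal) {
      cls <- c("absent", "present")
      yp <- match(binarize_tremor(test_ds$class_names[yp]), cls)
      yt <- match(binarize_tremor(test_ds$class_names[yt]), cls)
    } else {
      cls <- test_ds$class_names
    }
    O <- task_error_table(task, yp, yt, cls)
    E <- expected_counts(O)
    error_table <- list(observed = O, expected = E,
                        flagged = flag_deviations(O, E))
  }

  structure(list(reports = reports, run_scores = run_scores,
                 comparison = comparison, error_table = error_table,
                 manifest = manifest, split = split),
            class = "experiment_result")
}

#' Select the run approximating median performance
#'
#' With ten runs the fourth-best by the metric is returned (the reference
#' protocol's median approximation); otherwise the `ceiling(n / 2)`-th best.
#' Ties break towards the lowest run id.
#'
#' @param run_scores Data frame with columns `run` and the metric (e.g. from
#'   `run_experiment()$run_scores`, one model's rows).
#' @param metric Metric column name; `"map"` by default.
#' @return The selected run id.
#' @export
select_median_run <- function(run_scores, metric = "map") {
  stopifnot(nrow(run_scores) >= 1, metric %in% names(run_scores))
  ord <- order(-run_scores[[metric]], run_scores$run)
  rank_wanted <- if (nrow(run_scores) == 10) 4L else ceiling(nrow(run_scores) / 2)
  run_scores$run[ord[rank_wanted]]
}

#' Write run scores as CSV
#'
#' @param run_scores Data frame of per-run scores.
#' @param path Output file.
#' @export
write_run_scores <- function(run_scores, path) {
  utils::write.csv(run_scores, path, row.names = FALSE)
  invisible(path)
}

#' Write a model comparison report as JSON
#'
#' @param comparison Data frame from [compare_models()].
#' @param path Output file.
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(comparison, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
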