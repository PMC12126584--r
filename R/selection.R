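# Per-patient class tallies used as the stratification target. `items` is a
# data.frame with columns patient_id, label, weight (window count or duration).
patient_class_table <- function(patient_id, label, weight = NULL) {
  if (is.null(weight)) weight <- rep(1, length(label))
  tab <- tapply(weight, list(patient_id, label), sum, default = 0)
  tab[is.na(tab)] <- 0
  tab
}

# Greedy bin packing: assign patients (largest first) to the bin minimising
# the squared deviation of per-class totals from the bin's target share.
greedy_assign <- function(tab, fractions, capacity = NULL) {
  n_bins <- length(fractions)
  totals <- colSums(tab)
  targets <- outer(fractions, totals)            # n_bins x n_classes
  bin_counts <- matrix(0, n_bins, ncol(tab))
  bin_n <- integer(n_bins)
  assignment <- integer(nrow(tab))
  ord <- order(rowSums(tab), decreasing = TRUE)
  for (i in ord) {
    cost <- rep(Inf, n_bins)
    for (b in seq_len(n_bins)) {
      if (!is.null(capacity) && bin_n[b] >= capacity[b]) next
      after <- bin_counts[b, ] + tab[i, ] - targets[b, ]
      before <- bin_counts[b, ] - targets[b, ]
      # marginal increase in squared deviation from the bin's target
      cost[b] <- sum((after^2 - before^2) / pmax(totals, 1))
    }
    b <- which.min(cost)
    assignment[i] <- b
    bin_counts[b, ] <- bin_counts[b, ] + tab[i, ]
    bin_n[b] <- bin_n[b] + 1L
  }
  assignment
}

#' Grouped stratified holdout split
#'
#' Partitions patients (never individual windows) into train/validation/test
#' sets so that no patient appears in more than one set, while greedily
#' matching each set's per-class totals to the global class distribution.
#'
#' @param recordings List of `accel_recording`s.
#' @param fractions Numeric vector summing to 1, one entry per split; default
#'   `c(train = 0.7, val = 0.1, test = 0.2)`.
#' @param symptom Symptom whose class distribution is stratified on.
#' @param seed Seed controlling tie-breaking by patient shuffling.
#' @return Named list of character vectors of patient IDs, one per split.
#' @export
grouped_stratified_holdout <- function(recordings,
                                       fractions = c(train = 0.7, val = 0.1,
                                                     test = 0.2),
                                       symptom = "tremor", seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  pid <- vapply(recordings, `[[`, "", "patient_id")
  lab <- vapply(recordings, function(r) as.character(r[[symptom]]), "")
  dur <- vapply(recordings, function(r) ncol(r$acc) / r$fs_hz, 0)
  patients <- unique(pid)
  if (length(patients) < length(fractions)) {
    stop("fewer patients (", length(patients), ") than splits (",
         length(fractions), ")")
  }
  tab <- with_seed(seed, {
    tab <- patient_class_table(pid, lab, dur)
    tab[sample(nrow(tab)), , drop = FALSE]  # shuffled tie-breaking
  })
  assignment <- greedy_assign(tab, fractions)
  out <- lapply(seq_along(fractions), function(b) rownames(tab)[assignment == b])
  names(out) <- names(fractions) %||% paste0("split", seq_along(fractions))
  out
}

#' Grouped stratified k-fold cross-validation folds
#'
#' Assigns whole patients to `k` folds, largest patients first, each to the
#' fold that minimises class-distribution divergence, under the hard
#' constraint that fold sizes differ by at most one patient. Every patient
#' lands in exactly one fold's validation set.
#'
#' @param dataset A `windowed_dataset` (stratification counts windows per
#'   class) or a list of `accel_recording`s (counts duration).
#' @param k Number of folds (>= 2); 5 by default.
#' @param seed Seed controlling tie-breaking.
#' @return List of `k` fold specs: `list(fold_id, train_patients,
#'   val_patients)`.
#' @export
grouped_stratified_kfold <- function(dataset, k = 5, seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (inherits(dataset, "windowed_dataset")) {
    pid <- dataset$patient_id
    lab <- dataset$class_names[dataset$label]
    wt <- rep(1, length(pid))
  } else {
    pid <- vapply(dataset, `[[`, "", "patient_id")
    lab <- vapply(dataset, function(r) as.character(r$tremor), "")
    wt <- vapply(dataset, function(r) ncol(r$acc) / r$fs_hz, 0)
  }
  patients <- unique(pid)
  if (length(patients) < k) stop("need at least k patients for k folds")
  tab <- with_seed(seed, {
    tab <- patient_class_table(pid, lab, wt)
    tab[sample(nrow(tab)), , drop = FALSE]
  })
  n <- nrow(tab)
  capacity <- rep(floor(n / k), k)
  extra <- n - sum(capacity)
  if (extra > 0) capacity[seq_len(extra)] <- capacity[seq_len(extra)] + 1L
  assignment <- greedy_assign(tab, rep(1 / k, k), capacity = capacity)
  lapply(seq_len(k), function(b) {
    list(fold_id = b,
         train_patients = rownames(tab)[assignment != b],
         val_patients = rownames(tab)[assignment == b])
  })
}

#' Sample the random-search hyperparameter space
#'
#' Draws `n_trials` hyperparameter settings for the Inception-network search:
#' window length uniform on `[3, 30]` seconds (with replacement), filter
#' length an integer from 8 to 255, depth an integer from 1 to 11, and the
#' number of filters a power of two from 2 to 64 -- the latter three sampled
#' uniformly without replacement, refilling an axis's pool once exhausted.
#'
#' @param n_trials Number of trials (>= 1); 60 by default.
#' @param seed Seed; the sampled list is deterministic given it.
#' @return List of `n_trials` lists with elements `window_length_s`,
#'   `filter_length`, `depth`, `n_filters`.
#' @export
sample_search_space <- function(n_trials = 60, seed = 1L) {
  stopifnot(n_trials >= 1)
  draw_no_replace <- function(pool, n) {
    out <- numeric(0)
    while (length(out) < n) {
      take <- min(n - length(out), length(pool))
      out <- c(out, sample(pool, take, replace = FALSE))
    }
    out
  }
  with_seed(seed, {
    wl <- stats::runif(n_trials, 3, 30)
    fl <- draw_no_replace(8:255, n_trials)
    dp <- draw_no_replace(1:11, n_trials)
    nf <- draw_no_replace(2^(1:6), n_trials)
    lapply(seq_len(n_trials), function(i) {
      list(window_length_s = wl[i], filter_length = as.integer(fl[i]),
           depth = as.integer(dp[i]), n_filters = as.integer(nf[i]))
    })
  })
}

#' Run (or enumerate) a random search over cross-validation folds
#'
#' Schedules exactly `length(trials) * length(folds)` model fits. For each
#' job, `trainer(hyperparams, fold)` fits a model and `scorer(model, fold)`
#' returns a validation score; scores are averaged across folds per trial.
#' A failing fit marks the trial failed and the search continues. In dry-run
#' mode the jobs are enumerated without fitting.
#'
#' @param trials List of hyperparameter maps (see [sample_search_space()]).
#' @param folds List of fold specs (see [grouped_stratified_kfold()]).
#' @param trainer,scorer Functions as described; ignored when `dry_run`.
#' @param dry_run If TRUE, only enumerate jobs.
#' @return List with `jobs` (data frame of trial_id, fold_id, status) and,
#'   unless dry-run, `records`: per-trial lists with `hyperparams`,
#'   `fold_scores`, `mean_score`, `failed`.
#' @export
run_search <- function(trials, folds, trainer = NULL, scorer = NULL,
                       dry_run = FALSE) {
  jobs <- expand.grid(fold_id = seq_along(folds),
                      trial_id = seq_along(trials))[, c("trial_id", "fold_id")]
  jobs$status <- "scheduled"
  if (dry_run) return(list(jobs = jobs, records = NULL))
  stopifnot(is.function(trainer), is.function(scorer))
  records <- vector("list", length(trials))
  for (ti in seq_along(trials)) {
    scores <- rep(NA_real_, length(folds))
    failed <- FALSE
    for (fi in seq_along(folds)) {
      row <- which(jobs$trial_id == ti & jobs$fold_id == fi)
      res <- tryCatch({
        model <- trainer(trials[[ti]], folds[[fi]])
        scorer(model, folds[[fi]])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        jobs$status[row] <- paste0("failed: ", conditionMessage(res))
        failed <- TRUE
      } else {
        scores[fi] <- res
        jobs$status[row] <- "done"
      }
    }
    records[[ti]] <- list(trial_id = ti, hyperparams = trials[[ti]],
                          fold_scores = scores,
                          mean_score = if (failed) NA_real_ else mean(scores),
                          failed = failed)
  }
  list(jobs = jobs, records = records)
}
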