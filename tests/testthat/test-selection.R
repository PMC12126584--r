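test_that("holdout splits are patient-disjoint and need enough patients", {
  co <- generate_cohort(tiny_cohort_config(n_patients = 1))
  expect_error(grouped_stratified_holdout(co, c(0.5, 0.3, 0.2)), "fewer")
  co6 <- generate_cohort(tiny_cohort_config(n_patients = 6))
  sp <- grouped_stratified_holdout(co6, c(train = 0.5, val = 0.2, test = 0.3),
                                   seed = 1)
  all_pat <- unname(unlist(sp))
  expect_equal(sort(all_pat), sort(unique(vapply(co6, `[[`, "", "patient_id"))))
  expect_equal(anyDuplicated(all_pat), 0)
})

test_that("holdout stratification keeps class proportions near global", {
  cfg <- cohort_config(n_patients = 30,
                       task_catalog = task_catalog_default()[1:4, ],
                       repetitions_per_task = 2,
                       duration_mean_s = 8, duration_sd_s = 1,
                       duration_min_s = 5,
                       symptom_prevalence = list(
                         tremor = c("0" = 0.5, "1" = 0.5, "2" = 0, "3" = 0,
                                    "4" = 0),
                         bradykinesia = c(no = 0.5, yes = 0.5),
                         dyskinesia = c(no = 0.5, yes = 0.5)),
                       seed = 8)
  co <- generate_cohort(cfg)
  sp <- grouped_stratified_holdout(co, c(train = 0.7, val = 0.1, test = 0.2),
                                   symptom = "bradykinesia", seed = 3)
  pid <- vapply(co, `[[`, "", "patient_id")
  lab <- vapply(co, `[[`, NA, "bradykinesia")
  global <- mean(lab)
  for (s in sp) {
    expect_lt(abs(mean(lab[pid %in% s]) - global), 0.10)
  }
})

test_that("k-fold puts every patient in exactly one validation fold", {
  cfg <- tiny_cohort_config(n_patients = 25, n_tasks = 2)
  co <- generate_cohort(cfg)
  folds <- grouped_stratified_kfold(co, k = 5, seed = 1)
  vals <- lapply(folds, `[[`, "val_patients")
  expect_equal(vapply(vals, length, 0L), rep(5L, 5))  # 20% each
  expect_equal(anyDuplicated(unlist(vals)), 0)
  expect_length(unlist(vals), 25)
  for (f in folds) {
    expect_length(intersect(f$train_patients, f$val_patients), 0)
  }
  expect_error(grouped_stratified_kfold(co, k = 1), "at least 2")
})

test_that("k-fold assignment is deterministic and order-invariant", {
  co <- generate_cohort(tiny_cohort_config(n_patients = 12, n_tasks = 3))
  f1 <- grouped_stratified_kfold(co, k = 4, seed = 9)
  f2 <- grouped_stratified_kfold(co, k = 4, seed = 9)
  expect_identical(f1, f2)
  shuffled <- co[rev(seq_along(co))]
  f3 <- grouped_stratified_kfold(shuffled, k = 4, seed = 9)
  expect_identical(lapply(f1, function(f) sort(f$val_patients)),
                   lapply(f3, function(f) sort(f$val_patients)))
})

test_that("no patient leaks between a fold's train and val windows", {
  co <- generate_cohort(easy_cohort_config(seed = 4, n_patients = 8))
  ds <- windowed_dataset(co, "tremor", 5, 0.5)
  folds <- grouped_stratified_kfold(ds, k = 4, seed = 2)
  for (f in folds) {
    tr_pat <- unique(ds$patient_id[ds$patient_id %in% f$train_patients])
    va_pat <- unique(ds$patient_id[ds$patient_id %in% f$val_patients])
    expect_length(intersect(tr_pat, va_pat), 0)
  }
})

test_that("search-space samples respect the stated ranges", {
  trials <- sample_search_space(60, seed = 5)
  expect_length(trials, 60)
  wl <- vapply(trials, `[[`, 0, "window_length_s")
  expect_true(all(wl >= 3 & wl <= 30))
  fl <- vapply(trials, `[[`, 0L, "filter_length")
  expect_true(all(fl >= 8 & fl <= 255))
  dp <- vapply(trials, `[[`, 0L, "depth")
  expect_true(all(dp >= 1 & dp <= 11))
  nf <- vapply(trials, `[[`, 0L, "n_filters")
  expect_true(all(nf %in% 2^(1:6)))
  # without-replacement: within each pool cycle all values distinct
  expect_equal(sort(nf[1:6]), 2^(1:6))
  expect_equal(length(unique(dp[1:11])), 11)
  expect_identical(trials, sample_search_space(60, seed = 5))
  expect_false(identical(trials, sample_search_space(60, seed = 6)))
})

test_that("search driver schedules trials x folds fits", {
  trials <- sample_search_space(60, seed = 1)
  folds <- replicate(5, list(fold_id = 1), simplify = FALSE)
  dry <- run_search(trials, folds, dry_run = TRUE)
  expect_equal(nrow(dry$jobs), 300)
  expect_true(all(dry$jobs$status == "scheduled"))

  small <- run_search(sample_search_space(1, seed = 1), folds,
                      trainer = function(hp, fold) hp,
                      scorer = function(model, fold) 0.7)
  expect_equal(nrow(small$jobs), 5)
  expect_equal(small$records[[1]]$mean_score, 0.7)
  # constant scorer: all trial means equal
  multi <- run_search(sample_search_space(3, seed = 2), folds,
                      trainer = function(hp, fold) hp,
                      scorer = function(model, fold) 0.5)
  expect_equal(vapply(multi$records, `[[`, 0, "mean_score"), rep(0.5, 3))
})

test_that("a failing fit marks the trial failed and the search continues", {
  folds <- replicate(2, list(fold_id = 1), simplify = FALSE)
  trials <- sample_search_space(3, seed = 3)
  calls <- 0
  res <- run_search(trials, folds,
                    trainer = function(hp, fold) {
                      calls <<- calls + 1
                      if (calls <= 2) stop("diverged") else hp
                    },
                    scorer = function(model, fold) 1)
  expect_true(res$records[[1]]$failed)
  expect_true(is.na(res$records[[1]]$mean_score))
  expect_false(res$records[[2]]$failed)
  expect_equal(res$records[[3]]$mean_score, 1)
  expect_true(any(grepl("failed: diverged", res$jobs$status)))
})
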