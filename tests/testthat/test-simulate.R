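test_that("cohort size is patients x tasks x repetitions", {
  co <- generate_cohort(tiny_cohort_config(n_patients = 2, n_tasks = 3,
                                           reps = 1))
  expect_length(co, 6)
  co2 <- generate_cohort(tiny_cohort_config(n_patients = 3, n_tasks = 2,
                                            reps = 2))
  expect_length(co2, 12)
})

test_that("cohorts are a pure function of (config, seed)", {
  cfg <- tiny_cohort_config(seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a, `[[`, "acc"), lapply(b, `[[`, "acc"))
  expect_identical(vapply(a, `[[`, 0, "tremor"), vapply(b, `[[`, 0, "tremor"))
  cfg2 <- tiny_cohort_config(seed = 14)
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a[[1]]$acc, c2[[1]]$acc))
})

test_that("recording durations follow the truncated normal", {
  cfg <- cohort_config(n_patients = 40,
                       task_catalog = task_catalog_default(),
                       repetitions_per_task = 2,
                       duration_mean_s = 29.2, duration_sd_s = 11.6,
                       duration_min_s = 5, seed = 3)
  co <- generate_cohort(cfg)
  durs <- vapply(co, function(r) ncol(r$acc) / r$fs_hz, 0)
  # analytic mean of N(29.2, 11.6^2) truncated below at 5
  a <- (5 - 29.2) / 11.6
  mu_trunc <- 29.2 + 11.6 * stats::dnorm(a) / (1 - stats::pnorm(a))
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - mu_trunc), 3 * se)
})

test_that("symptom label prevalence matches the configured table", {
  cfg <- cohort_config(n_patients = 60,
                       task_catalog = task_catalog_default(),
                       repetitions_per_task = 1,
                       duration_mean_s = 8, duration_sd_s = 1,
                       duration_min_s = 5, seed = 5)
  co <- generate_cohort(cfg)
  prev <- symptom_prevalence_default()
  n <- length(co)
  trem <- vapply(co, `[[`, 0, "tremor")
  for (sev in 0:2) {  # severities with non-tiny expected counts
    p <- prev$tremor[[as.character(sev)]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(trem == sev) - p), 3 * se + 1e-12)
  }
  p_dys <- prev$dyskinesia[["yes"]]
  se <- sqrt(p_dys * (1 - p_dys) / n)
  expect_lt(abs(mean(vapply(co, `[[`, NA, "dyskinesia")) - p_dys), 3 * se)
})

test_that("tremor band power is monotone in severity over paired draws", {
  prof <- task_catalog_default()[14, ]  # standing: quiet baseline
  bp <- sapply(1:100, function(s) {
    vapply(c(0, 1, 2, 3), function(sev) {
      acc <- synthesize_signal(prof, sev, FALSE, FALSE, 10, 50, seed = s)
      welch_band_power(sqrt(colSums(acc^2)), 50, c(4, 6))
    }, 0)
  })
  means <- rowMeans(bp)
  expect_true(all(diff(means) > 0))
  # severity 3 vs 1, same seed: strictly greater band power in most pairs
  expect_gt(mean(bp[4, ] > bp[2, ]), 0.95)
})

test_that("zero-severity draws are identical to the symptom-free baseline", {
  prof <- task_catalog_default()[1, ]
  a <- synthesize_signal(prof, 0, FALSE, FALSE, 8, 50, seed = 42)
  b <- synthesize_signal(prof, 0, FALSE, FALSE, 8, 50, seed = 42)
  expect_identical(a, b)
  expect_true(all(is.finite(a)))
  expect_equal(ncol(a), 400)
})

test_that("bradykinesia lowers the magnitude standard deviation", {
  prof <- task_catalog_default()[10, ]  # walking straight
  sds <- sapply(1:100, function(s) {
    on <- synthesize_signal(prof, 0, TRUE, FALSE, 8, 50, seed = s)
    off <- synthesize_signal(prof, 0, FALSE, FALSE, 8, 50, seed = s)
    c(brady = magnitude_stats(on)$sd, free = magnitude_stats(off)$sd)
  })
  expect_gt(mean(sds["free", ] > sds["brady", ]), 0.95)
  d <- sds["free", ] - sds["brady", ]
  expect_gt(mean(d), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("dyskinesia adds low-frequency band power", {
  prof <- task_catalog_default()[14, ]
  bp <- sapply(1:50, function(s) {
    on <- synthesize_signal(prof, 0, FALSE, TRUE, 8, 50, seed = s)
    off <- synthesize_signal(prof, 0, FALSE, FALSE, 8, 50, seed = s)
    c(on = welch_band_power(sqrt(colSums(on^2)), 50, c(1, 4)),
      off = welch_band_power(sqrt(colSums(off^2)), 50, c(1, 4)))
  })
  expect_gt(mean(bp["on", ] > bp["off", ]), 0.9)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(sampling_hz = 0), "sampling_hz")
  expect_error(cohort_config(duration_min_s = 0), "duration_min_s")
  bad_prev <- symptom_prevalence_default()
  bad_prev$tremor <- c("0" = 0.5, "1" = 0.4, "2" = 0.2, "3" = 0, "4" = 0)
  expect_error(cohort_config(symptom_prevalence = bad_prev), "sum to 1")
  expect_error(cohort_config(effect_scales = list(
    tremor_amp = 1, dyskinesia_amp = 1, brady_attenuation = 1.2)),
    "brady_attenuation")
})

test_that("cohort CSV writer and reader round-trip", {
  co <- generate_cohort(tiny_cohort_config(n_patients = 2, n_tasks = 2))
  dir <- tempfile("cohort")
  write_cohort_csv(co, dir)
  expect_true(file.exists(file.path(dir, "samples.csv")))
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_cohort_csv(dir, fs_hz = 50)
  expect_length(back, length(co))
  key <- function(r) paste(r$patient_id, r$task, r$repetition)
  m <- match(vapply(co, key, ""), vapply(back, key, ""))
  for (i in seq_along(co)) {
    expect_equal(back[[m[i]]]$acc, co[[i]]$acc, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(back[[m[i]]]$tremor, co[[i]]$tremor)
    expect_equal(back[[m[i]]]$bradykinesia, co[[i]]$bradykinesia)
  }
  unlink(dir, recursive = TRUE)
})
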