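# Shared fixture builders. All fixtures are generated in code at test time.

# Small cohort for structural tests.
tiny_cohort_config <- function(seed = 7, n_patients = 4, n_tasks = 3,
                               reps = 1) {
  cohort_config(
    n_patients = n_patients,
    task_catalog = task_catalog_default()[seq_len(n_tasks), ],
    repetitions_per_task = reps,
    duration_mean_s = 12, duration_sd_s = 3, duration_min_s = 6,
    seed = seed
  )
}

# "Easy" cohort: boosted tremor amplitude and symptom prevalence so the
# classifiers face a clearly learnable task at desk scale.
easy_cohort_config <- function(seed = 11, n_patients = 10) {
  cohort_config(
    n_patients = n_patients,
    task_catalog = task_catalog_default()[c(1, 3, 10, 14), ],
    repetitions_per_task = 2,
    duration_mean_s = 12, duration_sd_s = 3, duration_min_s = 6,
    symptom_prevalence = list(
      tremor = c("0" = 0.5, "1" = 0.3, "2" = 0.15, "3" = 0.04, "4" = 0.01),
      bradykinesia = c(no = 0.5, yes = 0.5),
      dyskinesia = c(no = 0.7, yes = 0.3)),
    effect_scales = list(tremor_amp = 2.5, dyskinesia_amp = 1.5,
                         brady_attenuation = 0.45),
    seed = seed
  )
}

# Bradykinesia-only cohort (single task, other symptoms switched off) used
# to validate amplitude-signature learning in isolation.
brady_cohort_config <- function(seed = 21, n_patients = 10, reps = 4) {
  cohort_config(
    n_patients = n_patients,
    task_catalog = task_catalog_default()[10, , drop = FALSE],
    repetitions_per_task = reps,
    duration_mean_s = 10, duration_sd_s = 2, duration_min_s = 6,
    symptom_prevalence = list(
      tremor = c("0" = 1, "1" = 0, "2" = 0, "3" = 0, "4" = 0),
      bradykinesia = c(no = 0.5, yes = 0.5),
      dyskinesia = c(no = 1, yes = 0)),
    effect_scales = list(tremor_amp = 2.5, dyskinesia_amp = 1.5,
                         brady_attenuation = 0.4),
    seed = seed
  )
}

# Collapse a merged tremor dataset to presence/absence.
binarize_dataset <- function(ds) {
  pres <- binarize_tremor(ds$class_names[ds$label])
  ds$class_names <- c("absent", "present")
  ds$label <- match(pres, ds$class_names)
  ds
}

# Grouped train/test split of a windowed dataset by patient.
split_by_patients <- function(cohort, ds, symptom, seed = 2,
                              fractions = c(train = 0.7, test = 0.3)) {
  sp <- grouped_stratified_holdout(cohort, fractions, symptom, seed = seed)
  list(train = filter_patients(ds, sp$train),
       test = filter_patients(ds, sp$test))
}

# Synthetic array dataset with a 5 Hz class signature, for network tests.
make_sine_dataset <- function(n_per_class = 20, L = 100, fs = 50, seed = 1,
                              amp = 2) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- array(stats::rnorm(n * 3 * L), dim = c(n, 3, L))
  y <- rep(1:2, each = n_per_class)
  tt <- (seq_len(L) - 1) / fs
  for (i in which(y == 2)) {
    ph <- stats::runif(1, 0, 2 * pi)
    X[i, 1, ] <- X[i, 1, ] + amp * sin(2 * pi * 5 * tt + ph)
  }
  structure(list(X = X, label = y, class_names = c("a", "b"),
                 patient_id = paste0("p", rep(seq_len(n), 1)),
                 task = rep("t", n), source_offset = rep(0L, n),
                 symptom = "bradykinesia", fs_hz = fs),
            class = "windowed_dataset")
}

# 3 SE of a balanced-accuracy estimate around 0.5 given per-class counts.
ba_3se <- function(n0, n1) 3 * 0.5 * sqrt(1 / (4 * n0) + 1 / (4 * n1))
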