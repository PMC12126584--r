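#' Default catalog of motor-task profiles
#'
#' A battery of 18 activities of daily living performed under clinical
#' observation, each with a frequency band and intensity scale for the
#' voluntary (non-symptomatic) wrist motion it induces, and a flag for tasks
#' requiring fine motor coordination. Intensities are acceleration scales in
#' m/s^2; bands are in Hz and must lie below the Nyquist frequency.
#'
#' @return A data frame with columns `name`, `band_lo_hz`, `band_hi_hz`,
#'   `base_intensity`, `fine_motor`.
#' @export
task_catalog_default <- function() {
  tasks <- rbind(
    c("drawing",                  0.5, 3.0, 0.60, TRUE),
    c("writing",                  0.5, 3.0, 0.55, TRUE),
    c("typing",                   1.0, 4.0, 0.50, TRUE),
    c("nuts-and-bolts assembly",  0.5, 3.5, 0.70, TRUE),
    c("drinking",                 0.3, 2.5, 0.65, TRUE),
    c("organizing papers",        0.5, 3.0, 0.80, TRUE),
    c("folding towels",           0.3, 2.5, 0.85, FALSE),
    c("buttoning a shirt",        0.5, 3.5, 0.55, TRUE),
    c("opening a bottle",         0.5, 3.0, 0.60, TRUE),
    c("walking straight",         0.8, 3.5, 2.40, FALSE),
    c("walking down a passage",   0.8, 3.5, 1.70, FALSE),
    c("walking a narrow passage", 0.8, 3.5, 1.50, FALSE),
    c("walking upstairs",         0.8, 4.0, 2.00, FALSE),
    c("standing",                 0.1, 1.5, 0.25, FALSE),
    c("sitting",                  0.1, 1.0, 0.15, FALSE),
    c("standing up from a chair", 0.5, 3.0, 1.20, FALSE),
    c("alternating hand movements", 1.0, 5.0, 1.60, FALSE),
    c("finger tapping",           1.5, 6.5, 0.90, TRUE)
  )
  data.frame(
    name = tasks[, 1],
    band_lo_hz = as.numeric(tasks[, 2]),
    band_hi_hz = as.numeric(tasks[, 3]),
    base_intensity = as.numeric(tasks[, 4]),
    fine_motor = as.logical(tasks[, 5]),
    stringsAsFactors = FALSE
  )
}

#' Default symptom prevalence table
#'
#' Class probabilities per symptom, approximating the heavy imbalance typical
#' of in-clinic Parkinson's cohorts: most task performances show no or mild
#' tremor, severe tremor is very rare, dyskinesia is present in roughly 11%
#' of recording time, bradykinesia in roughly 30%.
#'
#' @return Named list with elements `tremor` (probabilities for severities
#'   0-4), `bradykinesia` and `dyskinesia` (probabilities for absent/present).
#' @export
symptom_prevalence_default <- function() {
  list(
    tremor = c("0" = 0.700, "1" = 0.215, "2" = 0.062, "3" = 0.019, "4" = 0.004),
    bradykinesia = c("no" = 0.70, "yes" = 0.30),
    dyskinesia = c("no" = 0.89, "yes" = 0.11)
  )
}

#' Cohort simulation configuration
#'
#' Bundles and validates everything [generate_cohort()] needs: the patient
#' count, task catalog, per-symptom prevalence, symptom effect scales and the
#' recording-duration distribution (truncated normal).
#'
#' @param n_patients Number of simulated patients.
#' @param task_catalog Data frame as returned by [task_catalog_default()].
#' @param repetitions_per_task Number of performances of each task per patient.
#' @param sampling_hz Sampling frequency in Hz.
#' @param duration_mean_s,duration_sd_s Mean and standard deviation of the
#'   recording duration in seconds before truncation.
#' @param duration_min_s Lower truncation of the duration in seconds.
#' @param symptom_prevalence Named list of per-symptom class probabilities;
#'   each element must sum to 1.
#' @param effect_scales Named list: `tremor_amp` (m/s^2 of tremor sinusoid
#'   amplitude per severity unit), `dyskinesia_amp` (m/s^2 scale of the 1-4 Hz
#'   dyskinetic component), `brady_attenuation` (multiplicative factor < 1
#'   applied to the voluntary component when bradykinesia is present).
#' @param seed Integer seed; identical (config, seed) yields a bit-identical
#'   cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 27,
                          task_catalog = task_catalog_default(),
                          repetitions_per_task = 2,
                          sampling_hz = 50,
                          duration_mean_s = 29.2,
                          duration_sd_s = 11.6,
                          duration_min_s = 5,
                          symptom_prevalence = symptom_prevalence_default(),
                          effect_scales = list(tremor_amp = 0.6,
                                               dyskinesia_amp = 0.8,
                                               brady_attenuation = 0.55),
                          seed = 1L) {
  stopifnot(n_patients >= 1, repetitions_per_task >= 1)
  if (sampling_hz <= 0) stop("sampling_hz must be positive")
  if (duration_min_s <= 0) stop("duration_min_s must be positive")
  if (!all(c("name", "band_lo_hz", "band_hi_hz", "base_intensity", "fine_motor")
           %in% names(task_catalog))) {
    stop("task_catalog is missing required columns")
  }
  bad_band <- task_catalog$band_lo_hz < 0 |
    task_catalog$band_lo_hz >= task_catalog$band_hi_hz |
    task_catalog$band_hi_hz >= sampling_hz / 2
  if (any(bad_band)) stop("task bands must satisfy 0 <= lo < hi < Nyquist")
  for (sym in c("tremor", "bradykinesia", "dyskinesia")) {
    p <- symptom_prevalence[[sym]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("symptom_prevalence[['", sym, "']] must be non-negative and sum to 1")
    }
  }
  if (!is.finite(effect_scales$brady_attenuation) ||
      effect_scales$brady_attenuation <= 0 || effect_scales$brady_attenuation >= 1) {
    stop("brady_attenuation must lie in (0, 1)")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    task_catalog = task_catalog,
    repetitions_per_task = as.integer(repetitions_per_task),
    sampling_hz = sampling_hz,
    duration_mean_s = duration_mean_s,
    duration_sd_s = duration_sd_s,
    duration_min_s = duration_min_s,
    symptom_prevalence = symptom_prevalence,
    effect_scales = effect_scales,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Band-limited Gaussian noise via FFT masking, rescaled to unit SD.
band_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  if (n < 8) return(w)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- (freqs >= lo & freqs <= hi) | (freqs >= fs - hi & freqs <= fs - lo)
  keep[1] <- FALSE
  if (!any(keep)) return(w)
  W <- stats::fft(w)
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) w else x / s
}

#' Synthesize one tri-axial wrist acceleration recording
#'
#' Additive signal model: a constant gravity offset with random fixed sensor
#' orientation, band-limited Gaussian voluntary motion in the task's frequency
#' band, an optional 4-6 Hz tremor sinusoid whose amplitude grows linearly
#' with severity, and optional 1-4 Hz band-limited dyskinetic noise.
#' Bradykinesia attenuates the voluntary component (factor
#' `effect_scales$brady_attenuation`) and mildly narrows its band towards low
#' frequencies, reproducing the lower magnitude standard deviation seen in
#' bradykinetic movement.
#'
#' @param profile One row of a task catalog (list or single-row data frame).
#' @param tremor Ordinal severity 0-4.
#' @param brady,dysk Logical presence flags.
#' @param duration_s Recording duration in seconds (>= 1/fs_hz).
#' @param fs_hz Sampling frequency in Hz.
#' @param seed Integer seed; the draw is a pure function of the arguments.
#' @param effect_scales As in [cohort_config()].
#' @return A 3 x T matrix of accelerations in m/s^2 (rows ax, ay, az).
#' @export
synthesize_signal <- function(profile, tremor, brady, dysk, duration_s, fs_hz,
                              seed,
                              effect_scales = list(tremor_amp = 0.6,
                                                   dyskinesia_amp = 0.8,
                                                   brady_attenuation = 0.55)) {
  stopifnot(duration_s >= 1 / fs_hz, tremor %in% 0:4,
            is.logical(brady) || brady %in% c(0, 1),
            is.logical(dysk) || dysk %in% c(0, 1))
  n <- round(duration_s * fs_hz)
  with_seed(seed, {
    tt <- (seq_len(n) - 1) / fs_hz

    # gravity: constant 9.81 m/s^2 along a random fixed orientation
    g <- stats::rnorm(3)
    g <- g / sqrt(sum(g^2)) * 9.81
    acc <- matrix(g, nrow = 3, ncol = n)

    # voluntary motion: per-axis band noise with random axis loading
    lo <- profile$band_lo_hz
    hi <- profile$band_hi_hz
    amp <- profile$base_intensity
    if (isTRUE(as.logical(brady))) {
      amp <- amp * effect_scales$brady_attenuation
      hi <- lo + 0.7 * (hi - lo)  # mild low-pass shift
    }
    loading <- abs(stats::rnorm(3)) + 0.2
    loading <- loading / sqrt(mean(loading^2))
    for (ax in 1:3) {
      acc[ax, ] <- acc[ax, ] + amp * loading[ax] * band_noise(n, fs_hz, lo, hi)
    }

    # tremor: 4-6 Hz sinusoid, amplitude linear in severity, random axis
    if (tremor > 0) {
      f_tr <- stats::runif(1, 4, 6)
      phase <- stats::runif(1, 0, 2 * pi)
      axis <- stats::rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      wave <- effect_scales$tremor_amp * tremor * sin(2 * pi * f_tr * tt + phase)
      acc <- acc + outer(axis, wave)
    }

    # dyskinesia: involuntary writhing as 1-4 Hz band noise
    if (isTRUE(as.logical(dysk))) {
      loading_d <- abs(stats::rnorm(3)) + 0.2
      loading_d <- loading_d / sqrt(mean(loading_d^2))
      for (ax in 1:3) {
        acc[ax, ] <- acc[ax, ] +
          effect_scales$dyskinesia_amp * loading_d[ax] * band_noise(n, fs_hz, 1, 4)
      }
    }
    rownames(acc) <- c("ax", "ay", "az")
    acc
  })
}

#' Generate a synthetic annotated cohort
#'
#' For each patient x task x repetition emits one [synthesize_signal()]
#' recording. Symptom labels are drawn once per patient-and-task from the
#' configured prevalence table (repetitions of the same task share labels,
#' as the same patient performing the same task does in a clinic visit).
#' Durations are truncated-normal draws. The result is a pure function of
#' `(config, config$seed)`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `accel_cohort`: a list of `accel_recording`
#'   objects (fields `patient_id`, `task`, `repetition`, `fs_hz`, `acc`
#'   (3 x T matrix), `tremor`, `bradykinesia`, `dyskinesia`), with the config
#'   attached as an attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tasks <- config$task_catalog
  prev <- config$symptom_prevalence
  recs <- with_seed(config$seed, {
    out <- vector("list",
                  config$n_patients * nrow(tasks) * config$repetitions_per_task)
    i <- 0L
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("patient%03d", p)
      for (ti in seq_len(nrow(tasks))) {
        tremor <- sample(0:4, 1, prob = prev$tremor)
        brady <- stats::runif(1) < prev$bradykinesia[["yes"]]
        dysk <- stats::runif(1) < prev$dyskinesia[["yes"]]
        for (rep_i in seq_len(config$repetitions_per_task)) {
          dur <- rtruncnorm_min(1, config$duration_mean_s, config$duration_sd_s,
                                config$duration_min_s)
          sseed <- child_seed(config$seed, i + 1L)
          acc <- synthesize_signal(tasks[ti, ], tremor, brady, dysk, dur,
                                   config$sampling_hz, sseed,
                                   config$effect_scales)
          i <- i + 1L
          out[[i]] <- structure(list(
            patient_id = pid, task = tasks$name[ti], repetition = rep_i,
            fs_hz = config$sampling_hz, acc = acc,
            tremor = tremor, bradykinesia = brady, dyskinesia = dysk
          ), class = "accel_recording")
        }
      }
    }
    out
  })
  structure(recs, class = "accel_cohort", config = config)
}

#' @export
print.accel_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Synthetic wrist accelerometer cohort:", length(x), "recordings,",
      cfg$n_patients, "patients,", nrow(cfg$task_catalog), "tasks at",
      cfg$sampling_hz, "Hz\n")
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' `write_cohort_csv()` writes two UTF-8 CSV files with header rows into
#' `dir`: `samples.csv` (patient_id, task, repetition, t_s, ax, ay, az) and
#' `labels.csv` (patient_id, task, repetition, tremor, bradykinesia,
#' dyskinesia). `read_cohort_csv()` reads the same dialect back into an
#' `accel_cohort`.
#'
#' @param cohort An `accel_cohort` (or plain list of `accel_recording`s).
#' @param dir Output/input directory.
#' @param fs_hz Sampling frequency used on read (samples carry time stamps,
#'   not the rate).
#' @return `write_cohort_csv()` the directory, invisibly;
#'   `read_cohort_csv()` an `accel_cohort`.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- do.call(rbind, lapply(cohort, function(r) {
    n <- ncol(r$acc)
    data.frame(patient_id = r$patient_id, task = r$task,
               repetition = r$repetition,
               t_s = (seq_len(n) - 1) / r$fs_hz,
               ax = r$acc[1, ], ay = r$acc[2, ], az = r$acc[3, ],
               stringsAsFactors = FALSE)
  }))
  labels <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, task = r$task,
               repetition = r$repetition, tremor = r$tremor,
               bradykinesia = r$bradykinesia, dyskinesia = r$dyskinesia,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir, fs_hz = 50) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  key <- function(d) paste(d$patient_id, d$task, d$repetition, sep = "\r")
  skey <- key(samples)
  recs <- lapply(seq_len(nrow(labels)), function(i) {
    rows <- samples[skey == key(labels[i, ]), ]
    rows <- rows[order(rows$t_s), ]
    structure(list(
      patient_id = labels$patient_id[i], task = labels$task[i],
      repetition = labels$repetition[i], fs_hz = fs_hz,
      acc = t(as.matrix(rows[, c("ax", "ay", "az")])),
      tremor = labels$tremor[i],
      bradykinesia = as.logical(labels$bradykinesia[i]),
      dyskinesia = as.logical(labels$dyskinesia[i])
    ), class = "accel_recording")
  })
  structure(recs, class = "accel_cohort")
}
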