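#' Remove recordings with missing or implausible annotations
#'
#' Filter semantics: recordings with a missing symptom label, a tremor rating
#' outside the ordinal 0-4 scale, or a non-boolean presence flag are dropped.
#' Valid recordings pass through unchanged.
#'
#' @param recordings List of `accel_recording` objects (or an `accel_cohort`).
#' @return List with elements `recordings` (the kept recordings, original
#'   class preserved) and `removed` (data frame of dropped indices and
#'   reasons).
#' @export
clean_annotations <- function(recordings) {
  reason <- character(length(recordings))
  for (i in seq_along(recordings)) {
    r <- recordings[[i]]
    if (is.null(r$tremor) || length(r$tremor) != 1 || is.na(r$tremor)) {
      reason[i] <- "missing tremor annotation"
    } else if (!(r$tremor %in% 0:4)) {
      reason[i] <- "tremor outside ordinal range 0-4"
    } else if (is.null(r$bradykinesia) || is.na(r$bradykinesia) ||
               !(is.logical(r$bradykinesia) || r$bradykinesia %in% c(0, 1))) {
      reason[i] <- "non-boolean bradykinesia flag"
    } else if (is.null(r$dyskinesia) || is.na(r$dyskinesia) ||
               !(is.logical(r$dyskinesia) || r$dyskinesia %in% c(0, 1))) {
      reason[i] <- "non-boolean dyskinesia flag"
    }
  }
  keep <- reason == ""
  kept <- recordings[keep]
  attributes(kept) <- attributes(recordings)[setdiff(names(attributes(recordings)), "names")]
  if (is.null(attr(kept, "class")) && !is.null(class(recordings))) {
    class(kept) <- class(recordings)
  }
  list(
    recordings = kept,
    removed = data.frame(index = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  )
}

#' Slide a fixed-length window over one recording
#'
#' Forward-sliding segmentation with 0-based, half-open sample indexing
#' `[start, start + L)`. Window starts are multiples of
#' `step = round(L * (1 - overlap_frac))` (half rounded away from zero); only
#' full windows are emitted, so recordings shorter than the window yield
#' nothing. Every window inherits the recording's labels.
#'
#' @param recording An `accel_recording`.
#' @param window_length_s Window length in seconds.
#' @param overlap_frac Overlap fraction in `[0, 1)`; 0.5 by default.
#' @return List of windows; each a list with `acc` (3 x L), `patient_id`,
#'   `task`, `source_offset` (0-based sample index), `tremor`,
#'   `bradykinesia`, `dyskinesia`.
#' @export
slide <- function(recording, window_length_s = 30, overlap_frac = 0.5) {
  stopifnot(window_length_s > 0, overlap_frac >= 0, overlap_frac < 1)
  L <- as.integer(round(window_length_s * recording$fs_hz))
  step <- as.integer(round_half_away(L * (1 - overlap_frac)))
  if (step == 0L) stop("window step computes to 0 samples; reduce overlap_frac")
  n <- ncol(recording$acc)
  if (n < L) return(list())
  starts <- seq.int(0L, n - L, by = step)
  lapply(starts, function(s) {
    list(acc = recording$acc[, (s + 1):(s + L), drop = FALSE],
         patient_id = recording$patient_id, task = recording$task,
         source_offset = s, tremor = recording$tremor,
         bradykinesia = recording$bradykinesia,
         dyskinesia = recording$dyskinesia)
  })
}

#' Build a labelled windowed dataset for one symptom
#'
#' Applies [slide()] to every recording and assembles an `N x 3 x L` array
#' with per-window class labels for the chosen symptom, patient group IDs and
#' provenance. Tremor labels are the ordinal severities as classes
#' `"0".."4"`; bradykinesia and dyskinesia are `"no"`/`"yes"`.
#'
#' @param recordings List of `accel_recording`s (clean them first with
#'   [clean_annotations()]).
#' @param symptom One of `"tremor"`, `"bradykinesia"`, `"dyskinesia"`.
#' @param window_length_s,overlap_frac Passed to [slide()].
#' @return Object of class `windowed_dataset`: list with `X` (array
#'   `N x 3 x L`), `label` (integer index into `class_names`), `class_names`,
#'   `patient_id`, `task`, `source_offset`, `symptom`, `fs_hz`.
#' @export
windowed_dataset <- function(recordings, symptom = c("tremor", "bradykinesia",
                                                     "dyskinesia"),
                             window_length_s = 30, overlap_frac = 0.5) {
  symptom <- match.arg(symptom)
  wins <- unlist(lapply(recordings, slide, window_length_s = window_length_s,
                        overlap_frac = overlap_frac), recursive = FALSE)
  if (length(wins) == 0) stop("no recording is long enough for the window")
  L <- ncol(wins[[1]]$acc)
  X <- array(0, dim = c(length(wins), 3L, L))
  for (i in seq_along(wins)) X[i, , ] <- wins[[i]]$acc
  class_names <- switch(symptom,
    tremor = c("0", "1", "2", "3", "4"),
    bradykinesia = c("no", "yes"),
    dyskinesia = c("no", "yes"))
  raw <- switch(symptom,
    tremor = vapply(wins, function(w) as.character(w$tremor), ""),
    bradykinesia = ifelse(vapply(wins, function(w) as.logical(w$bradykinesia),
                                 NA), "yes", "no"),
    dyskinesia = ifelse(vapply(wins, function(w) as.logical(w$dyskinesia),
                               NA), "yes", "no"))
  structure(list(
    X = X,
    label = match(raw, class_names),
    class_names = class_names,
    patient_id = vapply(wins, `[[`, "", "patient_id"),
    task = vapply(wins, `[[`, "", "task"),
    source_offset = vapply(wins, `[[`, 0L, "source_offset"),
    symptom = symptom,
    fs_hz = recordings[[1]]$fs_hz
  ), class = "windowed_dataset")
}

#' Merge tremor severities 3 and 4 into one class
#'
#' The most severe tremor examples are too short and too rare to train on
#' separately, so severities 3 and 4 are combined into a single class
#' `"3-4"`, giving class names `"0", "1", "2", "3-4"`.
#'
#' @param dataset A `windowed_dataset` with `symptom == "tremor"`.
#' @return The dataset with merged labels and updated `class_names`.
#' @export
merge_tremor_classes <- function(dataset) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  if (dataset$symptom != "tremor") {
    stop("merge_tremor_classes() applies only to tremor datasets")
  }
  old <- dataset$class_names[dataset$label]
  merged <- ifelse(old %in% c("3", "4"), "3-4", old)
  dataset$class_names <- c("0", "1", "2", "3-4")
  dataset$label <- match(merged, dataset$class_names)
  dataset
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat("Windowed dataset:", dim(x$X)[1], "windows of", dim(x$X)[3],
      "samples,", "symptom =", x$symptom,
      "(classes:", paste(x$class_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Restrict a windowed dataset to a set of patients
#'
#' Keeps the windows whose `patient_id` is in `patients`, with all metadata
#' aligned — the standard way to materialize a grouped split.
#'
#' @param dataset A `windowed_dataset`.
#' @param patients Character vector of patient IDs to keep.
#' @return The filtered `windowed_dataset`.
#' @export
filter_patients <- function(dataset, patients) {
  stopifnot(inherits(dataset, "windowed_dataset"))
  subset_windows(dataset, which(dataset$patient_id %in% patients))
}

# Subset a windowed dataset by window indices, keeping metadata aligned.
subset_windows <- function(dataset, idx) {
  dataset$X <- dataset$X[idx, , , drop = FALSE]
  dataset$label <- dataset$label[idx]
  dataset$patient_id <- dataset$patient_id[idx]
  dataset$task <- dataset$task[idx]
  dataset$source_offset <- dataset$source_offset[idx]
  dataset
}
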