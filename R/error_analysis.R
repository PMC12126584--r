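#' Expected task-level misclassification counts
#'
#' Given observed counts `O[t, yhat, y]` by motor task, predicted class and
#' true class, computes the counts expected if misclassifications were
#' uniformly distributed across tasks: the task's share of all samples at
#' true class `y`, times the total count at `(yhat, y)`. Summed over tasks,
#' expected and observed counts agree for every `(yhat, y)` cell by
#' construction.
#'
#' @param observed 3-D array `tasks x predicted x true` of non-negative
#'   counts (dimnames recommended).
#' @return Array of expected counts with the same shape. True classes with no
#'   samples yield zero expected counts, with a warning.
#' @export
expected_counts <- function(observed) {
  stopifnot(length(dim(observed)) == 3, all(observed >= 0))
  E <- array(0, dim = dim(observed), dimnames = dimnames(observed))
  n_true <- dim(observed)[3]
  for (y in seq_len(n_true)) {
    task_totals <- apply(observed[, , y, drop = FALSE], 1, sum)  # sum over yhat
    denom <- sum(task_totals)
    if (denom == 0) {
      warning("no samples at true class ", y, "; expected counts set to 0")
      next
    }
    class_totals <- apply(observed[, , y, drop = FALSE], 2, sum) # sum over t
    E[, , y] <- outer(task_totals / denom, class_totals)
  }
  E
}

#' Tabulate observed counts by task, predicted and true class
#'
#' @param task Character vector of task names per sample.
#' @param y_pred,y_true Integer class indices per sample.
#' @param class_names Class names (defines array extent).
#' @param tasks Optional fixed task ordering.
#' @return 3-D count array `tasks x predicted x true`.
#' @export
task_error_table <- function(task, y_pred, y_true, class_names,
                             tasks = sort(unique(task))) {
  K <- length(class_names)
  O <- array(0, dim = c(length(tasks), K, K),
             dimnames = list(task = tasks, predicted = class_names,
                             true = class_names))
  for (i in seq_along(task)) {
    O[task[i], y_pred[i], y_true[i]] <- O[task[i], y_pred[i], y_true[i]] + 1
  }
  O
}

#' Flag task/prediction cells with over- or under-represented errors
#'
#' A cell is reported when observed and expected counts differ by at least
#' 40% in either direction (`max(O, E) / min(O, E) >= min_ratio`) and both
#' counts are at least `min_count` instances.
#'
#' @param observed,expected 3-D arrays from [task_error_table()] /
#'   [expected_counts()].
#' @param min_ratio Ratio threshold; 1.4 by default.
#' @param min_count Count floor for both O and E; 10 by default.
#' @return Data frame with columns task, predicted, true, observed, expected.
#' @export
flag_deviations <- function(observed, expected, min_ratio = 1.4,
                            min_count = 10) {
  dn <- dimnames(observed)
  out <- data.frame(task = character(0), predicted = character(0),
                    true = character(0), observed = numeric(0),
                    expected = numeric(0), stringsAsFactors = FALSE)
  idx <- which(observed >= min_count & expected >= min_count, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    o <- observed[idx[r, 1], idx[r, 2], idx[r, 3]]
    e <- expected[idx[r, 1], idx[r, 2], idx[r, 3]]
    if (max(o, e) / min(o, e) >= min_ratio) {
      out <- rbind(out, data.frame(
        task = dn[[1]][idx[r, 1]], predicted = dn[[2]][idx[r, 2]],
        true = dn[[3]][idx[r, 3]], observed = o, expected = e,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Binarize ordinal tremor severity
#'
#' Maps severity 0 to `"absent"` and severities >= 1 (including the merged
#' `"3-4"` class) to `"present"`.
#'
#' @param labels Numeric severities or character class names.
#' @return Character vector of `"absent"`/`"present"`.
#' @export
binarize_tremor <- function(labels) {
  if (is.numeric(labels)) {
    ifelse(labels >= 1, "present", "absent")
  } else {
    ifelse(labels == "0", "absent", "present")
  }
}

#' Magnitude summary of a recording
#'
#' The magnitude series `sqrt(ax^2 + ay^2 + az^2)` and its standard
#' deviation, which is proportional to the signal's power and lower for
#' bradykinetic movement.
#'
#' @param recording An `accel_recording` or a 3 x T matrix.
#' @return List with `magnitude` (numeric series) and `sd` (m/s^2).
#' @export
magnitude_stats <- function(recording) {
  acc <- if (is.list(recording)) recording$acc else recording
  stopifnot(is.matrix(acc), ncol(acc) >= 2)
  mag <- sqrt(colSums(acc^2))
  list(magnitude = mag, sd = stats::sd(mag))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann window, 256-sample segments
#' (shortened to the series length when shorter) and 50% segment overlap.
#' One-sided density normalized so that the integral over frequency
#' approximates the signal variance.
#'
#' @param x Numeric series.
#' @param fs Sampling frequency in Hz.
#' @param nseg Segment length; 256 by default.
#' @param detrend Subtract the per-segment mean before windowing.
#' @return List with `freq` (Hz) and `density` (power per Hz).
#' @export
welch_psd <- function(x, fs, nseg = 256, detrend = TRUE) {
  n <- length(x)
  nseg <- min(nseg, n)
  if (nseg < 2) stop("series too short for spectral estimation")
  step <- max(1, floor(nseg / 2))
  starts <- seq(1, n - nseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, nseg - 1) / nseg))  # Hann
  U <- sum(w^2)
  n_freq <- nseg %/% 2 + 1
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    if (detrend) seg <- seg - mean(seg)
    X <- stats::fft(seg * w)[seq_len(n_freq)]
    p <- (Mod(X)^2) / (U * fs)
    # one-sided: double all bins except DC and (for even nseg) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(n_freq) - 1) * fs / nseg,
       density = acc / length(starts))
}

#' Band power from the Welch spectrum
#'
#' Trapezoidal integral of the Welch density over a frequency band; the
#' default 4-6 Hz band targets parkinsonian tremor.
#'
#' @param series Numeric series (e.g. an acceleration magnitude).
#' @param fs Sampling frequency in Hz.
#' @param band Length-2 numeric `(low, high)` in Hz, below Nyquist.
#' @return Scalar band power.
#' @export
welch_band_power <- function(series, fs, band = c(4, 6)) {
  if (band[2] > fs / 2) stop("band upper edge exceeds the Nyquist frequency")
  psd <- welch_psd(series, fs)
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(sel) < 2) return(sum(psd$density[sel]) * (psd$freq[2] - psd$freq[1]))
  f <- psd$freq[sel]
  d <- psd$density[sel]
  sum(diff(f) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
}

#' Sample entropy
#'
#' Negative log of the conditional probability that templates of length `m`
#' within Chebyshev tolerance `r` remain within tolerance at length `m + 1`,
#' excluding self-matches. Constant series return 0 (all templates match);
#' series with no template matches return `Inf` with a warning.
#'
#' @param series Numeric series of length > `m + 1`.
#' @param m Template length; 2 by default.
#' @param r Tolerance; `0.2 * sd(series)` by default.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  stopifnot(length(series) > m + 1)
  if (stats::sd(series) < 1e-12) return(0)
  val <- pracma::sample_entropy(series, edim = m, r = r, tau = 1)
  if (!is.finite(val) || is.nan(val)) {
    warning("no template matches; sample entropy undefined, reporting Inf")
    return(Inf)
  }
  val
}

#' Signal summary for the misclassification analysis
#'
#' @param recording An `accel_recording` or 3 x T matrix.
#' @param band Tremor band in Hz.
#' @return Object of class `signal_summary`: magnitude SD, sample entropy,
#'   Welch PSD and band power of the magnitude series.
#' @export
signal_summary <- function(recording, band = c(4, 6)) {
  acc <- if (is.list(recording)) recording$acc else recording
  fs <- if (is.list(recording)) recording$fs_hz else 50
  ms <- magnitude_stats(acc)
  psd <- welch_psd(ms$magnitude, fs)
  structure(list(
    sd = ms$sd,
    sample_entropy = sample_entropy(ms$magnitude),
    psd = psd,
    band_power = welch_band_power(ms$magnitude, fs, band)
  ), class = "signal_summary")
}
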