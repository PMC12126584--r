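#' Bundle predictions, scores and ground truth
#'
#' The common container consumed by every metric: per-sample class scores
#' (probabilities when `proba = TRUE`), the derived argmax prediction (ties
#' broken towards the first class), and optional ground-truth indices.
#'
#' @param y_true Integer class indices (1-based into `class_names`), or NULL.
#' @param scores N x K numeric matrix of class scores.
#' @param class_names Character vector of K class names.
#' @param proba Whether `scores` rows are probabilities summing to 1.
#' @return Object of class `prediction_set`.
#' @export
prediction_set <- function(y_true, scores, class_names, proba = TRUE) {
  scores <- as.matrix(scores)
  if (ncol(scores) != length(class_names)) {
    stop("scores must have one column per class")
  }
  if (!is.null(y_true)) {
    y_true <- as.integer(y_true)
    stopifnot(length(y_true) == nrow(scores),
              all(y_true >= 1 & y_true <= length(class_names)))
  }
  if (proba) {
    rs <- rowSums(scores)
    if (any(abs(rs - 1) > 1e-6)) stop("probability rows must sum to 1")
  }
  colnames(scores) <- class_names
  structure(list(y_true = y_true, scores = scores,
                 y_pred = max.col(scores, ties.method = "first"),
                 class_names = class_names, proba = proba),
            class = "prediction_set")
}

#' Balanced accuracy
#'
#' The mean of the per-class recalls; 0.5 is the expectation for a random
#' classifier on a binary task.
#'
#' @param pred A [prediction_set()] with ground truth.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(pred) {
  y <- pred$y_true
  present <- sort(unique(y))
  if (length(present) < 1) stop("no ground-truth labels")
  recalls <- vapply(present, function(cl) {
    mean(pred$y_pred[y == cl] == cl)
  }, 0)
  mean(recalls)
}

#' Accuracy
#' @param pred A [prediction_set()] with ground truth.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(pred) mean(pred$y_pred == pred$y_true)

#' Average precision and mean average precision
#'
#' `average_precision()` evaluates the recall-weighted mean of precision over
#' descending unique score thresholds, with the `R[-1] = 0` convention and no
#' interpolation: `AP = sum_i (R_i - R_{i-1}) P_i`. `mean_ap()` is the
#' unweighted mean of one-vs-rest per-class APs.
#'
#' @param pred A [prediction_set()] with scores and ground truth.
#' @param positive_class Class name or index treated as positive.
#' @return Scalar in `[0, 1]`.
#' @export
average_precision <- function(pred, positive_class) {
  if (is.character(positive_class)) {
    positive_class <- match(positive_class, pred$class_names)
  }
  s <- pred$scores[, positive_class]
  pos <- pred$y_true == positive_class
  n_pos <- sum(pos)
  if (n_pos == 0) stop("average precision undefined: no positive samples")
  thresholds <- sort(unique(s), decreasing = TRUE)
  r_prev <- 0
  ap <- 0
  for (th in thresholds) {
    sel <- s >= th
    precision <- sum(pos & sel) / sum(sel)
    recall <- sum(pos & sel) / n_pos
    ap <- ap + (recall - r_prev) * precision
    r_prev <- recall
  }
  ap
}

#' @rdname average_precision
#' @export
mean_ap <- function(pred) {
  aps <- vapply(seq_along(pred$class_names), function(k) {
    average_precision(pred, k)
  }, 0)
  mean(aps)
}

#' Macro-averaged F1 score
#'
#' Per-class one-vs-rest F1 (`2 P R / (P + R)`, defined as 0 when both
#' precision and recall are 0), averaged with equal class weights.
#'
#' @param pred A [prediction_set()] with ground truth.
#' @return Scalar in `[0, 1]`.
#' @export
f1_macro <- function(pred) {
  f1s <- vapply(seq_along(pred$class_names), function(cl) {
    tp <- sum(pred$y_pred == cl & pred$y_true == cl)
    fp <- sum(pred$y_pred == cl & pred$y_true != cl)
    fn <- sum(pred$y_pred != cl & pred$y_true == cl)
    if (tp == 0 && (fp + fn) >= 0 && (2 * tp + fp + fn) == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1s)
}

# Rank-statistic binary AUROC from positive-class scores.
auroc_binary <- function(scores_pos, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve (one-vs-one for multiclass)
#'
#' Binary tasks use the rank-statistic (Mann-Whitney) AUROC. Multiclass tasks
#' average, over all unordered class pairs, the two directed binary AUROCs
#' computed on the samples of that pair only; pairs with an absent class are
#' skipped with a warning.
#'
#' @param pred A [prediction_set()] with probability scores.
#' @return Scalar in `[0, 1]`.
#' @export
auroc <- function(pred) {
  y <- pred$y_true
  K <- length(pred$class_names)
  if (K == 2) {
    return(auroc_binary(pred$scores[, 2], y == 2))
  }
  pair_scores <- c()
  for (i in 1:(K - 1)) {
    for (j in (i + 1):K) {
      sel <- y %in% c(i, j)
      if (!any(y == i) || !any(y == j)) {
        warning("class pair (", pred$class_names[i], ", ",
                pred$class_names[j], ") skipped: absent class")
        next
      }
      a_ij <- auroc_binary(pred$scores[sel, i], y[sel] == i)
      a_ji <- auroc_binary(pred$scores[sel, j], y[sel] == j)
      pair_scores <- c(pair_scores, (a_ij + a_ji) / 2)
    }
  }
  mean(pair_scores)
}

#' Macro-averaged mean absolute error for ordinal tasks
#'
#' Per-class mean absolute error between predicted and true class index,
#' averaged with equal class weights (the macro-average of the per-class
#' MAE). `printed_form = TRUE` instead scales the sum of per-class MAEs by
#' `1/N`.
#'
#' @param pred A [prediction_set()] with ground truth on integer-coded
#'   ordinal classes.
#' @param printed_form Use the `1/N` prefactor variant.
#' @return Non-negative scalar.
#' @export
mamae <- function(pred, printed_form = FALSE) {
  y <- pred$y_true
  classes <- sort(unique(y))
  maes <- vapply(classes, function(cl) {
    mean(abs(pred$y_pred[y == cl] - cl))
  }, 0)
  if (printed_form) sum(maes) / length(y) else mean(maes)
}

#' Confusion matrix
#'
#' Counts with rows = true class, columns = predicted class; row sums equal
#' the per-class sample counts.
#'
#' @param pred A [prediction_set()] with ground truth.
#' @return K x K integer matrix with class-name dimnames.
#' @export
confusion <- function(pred) {
  K <- length(pred$class_names)
  m <- matrix(0L, K, K, dimnames = list(true = pred$class_names,
                                        predicted = pred$class_names))
  for (i in seq_along(pred$y_true)) {
    m[pred$y_true[i], pred$y_pred[i]] <- m[pred$y_true[i], pred$y_pred[i]] + 1L
  }
  m
}

# Reflected Gaussian kernel weights of observations f_i at grid points t,
# reflecting probability mass at the [0, 1] boundaries.
reflected_kernel <- function(t_grid, f, sigma) {
  k <- function(a, b) stats::dnorm(a - b, sd = sigma)
  w <- outer(t_grid, f, k) + outer(t_grid, -f, k) + outer(t_grid, 2 - f, k)
  w
}

# Smoothed calibration error at a fixed bandwidth.
smece_at <- function(f, y01, sigma, n_grid = 512) {
  t_grid <- seq(0, 1, length.out = n_grid)
  W <- reflected_kernel(t_grid, f, sigma)
  resid_num <- W %*% (y01 - f)      # per-grid kernel-weighted residual sum
  dt <- t_grid[2] - t_grid[1]
  # integral over t of |sum_i K(t - f_i)(y_i - f_i)| / n
  sum(abs(resid_num)) * dt / length(f)
}

#' Reliability curve and smoothed expected calibration error
#'
#' Regresses the conditional outcome frequency `E[y|f]` on the predicted
#' probability `f` with a reflected Gaussian kernel. The bandwidth is chosen
#' automatically as the fixed point `sigma = smECE_sigma` (bisection on
#' `[1e-3, 1]`, tolerance 1e-4), and the reported smECE is the
#' kernel-weighted mean absolute deviation of the smoothed curve from the
#' diagonal; lower is better calibrated.
#'
#' @param pred A binary-task [prediction_set()] with probabilities, or a list
#'   with numeric `f` (predicted probability of the positive class) and `y`
#'   (0/1 outcomes).
#' @param n_grid Evaluation grid size on `[0, 1]`.
#' @return Object of class `reliability_curve`: list with `f_grid`,
#'   `smoothed` (E[y|f] estimate), `density`, `bandwidth`, `smece`.
#' @export
reliability <- function(pred, n_grid = 512) {
  if (inherits(pred, "prediction_set")) {
    if (length(pred$class_names) != 2) {
      stop("reliability analysis applies to binary tasks")
    }
    f <- pred$scores[, 2]
    y01 <- as.numeric(pred$y_true == 2)
  } else {
    f <- pred$f
    y01 <- as.numeric(pred$y)
  }
  stopifnot(length(f) == length(y01), all(f >= -1e-9 & f <= 1 + 1e-9))
  f <- pmin(pmax(f, 0), 1)
  lo <- 1e-3
  hi <- 1
  g <- function(sigma) smece_at(f, y01, sigma, n_grid) - sigma
  # smECE_sigma is non-increasing in sigma, so g is strictly decreasing:
  # bisection finds the unique fixed point, with a bandwidth floor at 1e-3.
  if (g(lo) <= 0) {
    sigma <- lo
  } else if (g(hi) >= 0) {
    sigma <- hi
  } else {
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    sigma <- (lo + hi) / 2
  }
  t_grid <- seq(0, 1, length.out = n_grid)
  W <- reflected_kernel(t_grid, f, sigma)
  dens <- rowSums(W)
  smoothed <- as.numeric(W %*% y01) / pmax(dens, 1e-12)
  structure(list(f_grid = t_grid, smoothed = pmin(pmax(smoothed, 0), 1),
                 density = dens / sum(dens),
                 bandwidth = sigma,
                 smece = smece_at(f, y01, sigma, n_grid)),
            class = "reliability_curve")
}

#' Smoothed expected calibration error
#'
#' @inheritParams reliability
#' @return Scalar smECE (lower values indicate better calibration).
#' @export
smece <- function(pred, n_grid = 512) reliability(pred, n_grid)$smece

#' Full metric report for a prediction set
#'
#' @param pred A [prediction_set()] with ground truth.
#' @param ordinal Include MAMAE (integer-coded ordinal classes).
#' @return List of scalar metrics plus the confusion matrix.
#' @export
metric_report <- function(pred, ordinal = FALSE) {
  rep <- list(
    accuracy = accuracy(pred),
    balanced_accuracy = balanced_accuracy(pred),
    ap_per_class = vapply(seq_along(pred$class_names),
                          function(k) average_precision(pred, k), 0),
    map = mean_ap(pred),
    f1_macro = f1_macro(pred),
    auroc = auroc(pred),
    confusion = confusion(pred)
  )
  if (ordinal) rep$mamae <- mamae(pred)
  if (length(pred$class_names) == 2 && pred$proba) {
    rep$smece <- smece(pred)
  }
  rep
}

#' Write a metric report as JSON
#'
#' @param report List from [metric_report()].
#' @param path Output file.
#' @export
write_metric_report <- function(report, path) {
  report$confusion <- as.data.frame(as.table(report$confusion))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
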