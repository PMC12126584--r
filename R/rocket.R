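#' Generate a random convolutional kernel set
#'
#' Draws kernels with the transform's published default distributions:
#' lengths uniform on \{7, 9, 11\}; weights standard normal, mean-centred per
#' kernel; bias uniform on `[-1, 1]`; dilation `2^a` with `a` uniform on
#' `[0, log2((input_length - 1) / (length - 1))]`; zero padding on or off
#' with equal probability.
#'
#' @param n_kernels Number of kernels; 10000 by default.
#' @param input_length Length L of the series the kernels will convolve.
#' @param seed Integer seed; the set is a pure function of the arguments.
#' @return Object of class `kernel_set`: list with `weights` (list of
#'   numeric vectors), `lengths`, `biases`, `dilations`, `paddings`
#'   (logical), `n_kernels`, `input_length`, `seed`.
#' @export
generate_kernels <- function(n_kernels = 10000, input_length, seed = 1L) {
  if (input_length < 11) stop("input_length must be at least 11")
  candidate <- c(7L, 9L, 11L)
  with_seed(seed, {
    lengths <- sample(candidate, n_kernels, replace = TRUE)
    weights <- vector("list", n_kernels)
    dilations <- integer(n_kernels)
    for (k in seq_len(n_kernels)) {
      w <- stats::rnorm(lengths[k])
      weights[[k]] <- w - mean(w)
      a_max <- log2((input_length - 1) / (lengths[k] - 1))
      dilations[k] <- as.integer(floor(2^stats::runif(1, 0, a_max)))
    }
    biases <- stats::runif(n_kernels, -1, 1)
    paddings <- stats::runif(n_kernels) < 0.5
    structure(list(weights = weights, lengths = lengths, biases = biases,
                   dilations = dilations, paddings = paddings,
                   n_kernels = as.integer(n_kernels),
                   input_length = as.integer(input_length),
                   seed = as.integer(seed)),
              class = "kernel_set")
  })
}

#' Random convolutional kernel transform
#'
#' Convolves every kernel against every channel of every window independently
#' (after per-channel z-normalization of each window) and pools each
#' intermediate series to two scalars: the proportion of strictly positive
#' values (PPV) and the maximum. A 3-channel input with `n` kernels yields
#' `6n` features per window.
#'
#' @param dataset A `windowed_dataset`, or a bare array `N x C x L`.
#' @param kernels A `kernel_set` from [generate_kernels()].
#' @param normalize Per-channel z-normalization of each window before
#'   convolution (the transform's convention); TRUE by default.
#' @return Object of class `rocket_features`: list with `features`
#'   (`N x (2 * n_kernels * C)` matrix) and `provenance` (data frame with
#'   kernel id, channel, statistic).
#' @export
rocket_transform <- function(dataset, kernels, normalize = TRUE) {
  X <- if (inherits(dataset, "windowed_dataset")) dataset$X else dataset
  stopifnot(length(dim(X)) == 3)
  N <- dim(X)[1]; C <- dim(X)[2]; L <- dim(X)[3]
  if (L != kernels$input_length) {
    stop("kernel set was generated for input length ", kernels$input_length,
         " but windows have length ", L)
  }
  if (normalize) {
    for (n in seq_len(N)) X[n, , ] <- znorm_rows(matrix(X[n, , ], C, L))
  }
  wstart <- c(0L, cumsum(kernels$lengths))[seq_len(kernels$n_kernels)]
  feats <- rocket_transform_cpp(as.numeric(X), N, C, L,
                                unlist(kernels$weights), wstart,
                                kernels$lengths, kernels$biases,
                                kernels$dilations,
                                as.integer(kernels$paddings))
  prov <- data.frame(
    kernel = rep(seq_len(kernels$n_kernels), each = 2 * C),
    channel = rep(rep(seq_len(C), each = 2), kernels$n_kernels),
    statistic = rep(c("ppv", "max"), C * kernels$n_kernels),
    stringsAsFactors = FALSE
  )
  structure(list(features = feats, provenance = prov), class = "rocket_features")
}

# Closed-form one-vs-rest ridge on standardized features via SVD; targets are
# +/-1 one-hot columns. Returns list(coef K x P, intercept K).
ridge_solve <- function(Xs, Y, lambda) {
  sv <- svd(Xs)
  shrink <- sv$d / (sv$d^2 + lambda)
  coef <- sv$v %*% (shrink * (t(sv$u) %*% Y))
  coef
}

#' Fit the random-kernel classifier head
#'
#' Standardizes the pooled features (training statistics only) and fits a
#' one-vs-rest least-squares ridge classifier, choosing the regularization
#' strength from a 10-point log-spaced grid over `[1e-3, 1e3]` by internal
#' cross-validation: grouped 5-fold by patient when `groups` is given,
#' otherwise stratified by class.
#'
#' @param features `rocket_features` or a bare feature matrix.
#' @param labels Integer class indices (1-based) or factor.
#' @param groups Optional patient IDs for grouped internal CV.
#' @param class_names Optional class names; derived from labels otherwise.
#' @param lambda_grid Regularization grid.
#' @param n_folds Internal CV folds; 5 by default.
#' @param seed Seed for the internal fold assignment.
#' @return Object of class `rocket_model` with the kernels left to the
#'   caller; fields: `center`, `scale`, `coef`, `chosen_lambda`,
#'   `lambda_grid`, `cv_scores`, `class_names`.
#' @export
rocket_fit <- function(features, labels, groups = NULL, class_names = NULL,
                       lambda_grid = 10^seq(-3, 3, length.out = 10),
                       n_folds = 5, seed = 1L) {
  X <- if (inherits(features, "rocket_features")) features$features else features
  if (is.factor(labels)) {
    class_names <- class_names %||% levels(labels)
    y <- as.integer(labels)
  } else {
    y <- as.integer(labels)
    class_names <- class_names %||% as.character(sort(unique(y)))
  }
  K <- length(unique(y))
  if (K < 2) stop("need at least 2 classes to fit a classifier")
  if (nrow(X) < K) stop("need at least as many samples as classes")

  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  n_classes <- length(class_names)
  Y <- matrix(-1, nrow(X), n_classes)
  Y[cbind(seq_len(nrow(X)), y)] <- 1

  folds <- with_seed(seed, {
    if (!is.null(groups)) {
      gs <- unique(groups)
      gs <- sample(gs)
      fold_of_group <- rep(seq_len(min(n_folds, length(gs))),
                           length.out = length(gs))
      fold_of_group[match(groups, gs)]
    } else {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep(seq_len(n_folds), length.out = length(idx))
      }
      f
    }
  })
  n_eff <- max(folds)
  cv_acc <- matrix(NA_real_, n_eff, length(lambda_grid))
  for (fi in seq_len(n_eff)) {
    tr <- folds != fi
    if (length(unique(y[tr])) < 2 || !any(!tr)) next
    sv <- svd(Xs[tr, , drop = FALSE])
    UtY <- t(sv$u) %*% Y[tr, , drop = FALSE]
    Xv <- Xs[!tr, , drop = FALSE]
    for (li in seq_along(lambda_grid)) {
      coef <- sv$v %*% ((sv$d / (sv$d^2 + lambda_grid[li])) * UtY)
      pred <- max.col(Xv %*% coef, ties.method = "first")
      cv_acc[fi, li] <- mean(pred == y[!tr])
    }
  }
  mean_acc <- colMeans(cv_acc, na.rm = TRUE)
  chosen <- lambda_grid[which.max(mean_acc)]
  coef <- ridge_solve(Xs, Y, chosen)
  structure(list(center = center, scale = scale, coef = coef,
                 chosen_lambda = chosen, lambda_grid = lambda_grid,
                 cv_scores = mean_acc, class_names = class_names),
            class = "rocket_model")
}

#' Predict class probabilities from a fitted random-kernel model
#'
#' Computes ridge decision values (class likelihoods) and maps them through
#' the softmax so each row is a probability vector summing to 1.
#'
#' @param model A `rocket_model`.
#' @param features `rocket_features` or a feature matrix with the training
#'   dimensionality.
#' @param y_true Optional integer ground-truth labels to attach.
#' @return A [prediction_set()].
#' @export
rocket_predict <- function(model, features, y_true = NULL) {
  X <- if (inherits(features, "rocket_features")) features$features else features
  if (ncol(X) != length(model$center)) {
    stop("feature dimension ", ncol(X), " does not match the model (",
         length(model$center), ")")
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  scores <- Xs %*% model$coef
  proba <- softmax(scores)
  prediction_set(y_true = y_true, scores = proba,
                 class_names = model$class_names, proba = TRUE)
}

#' Train the full random-kernel pipeline on a windowed dataset
#'
#' Convenience wrapper: generates kernels for the dataset's window length,
#' transforms, and fits the ridge head with grouped internal CV.
#'
#' @param dataset A `windowed_dataset`.
#' @param n_kernels Number of kernels.
#' @param seed Seed for kernels and internal CV.
#' @param ... Passed to [rocket_fit()].
#' @return List of class `rocket_pipeline`: `kernels`, `model`,
#'   `class_names`.
#' @export
rocket_train <- function(dataset, n_kernels = 10000, seed = 1L, ...) {
  kernels <- generate_kernels(n_kernels, input_length = dim(dataset$X)[3],
                              seed = seed)
  feats <- rocket_transform(dataset, kernels)
  model <- rocket_fit(feats, dataset$label, groups = dataset$patient_id,
                      class_names = dataset$class_names, seed = seed, ...)
  structure(list(kernels = kernels, model = model,
                 class_names = dataset$class_names),
            class = "rocket_pipeline")
}

#' @rdname rocket_train
#' @param object A `rocket_pipeline`.
#' @param newdata A `windowed_dataset` to predict on.
#' @export
predict.rocket_pipeline <- function(object, newdata, ...) {
  feats <- rocket_transform(newdata, object$kernels)
  rocket_predict(object$model, feats, y_true = newdata$label)
}
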