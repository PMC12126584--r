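# Daubechies-4 (four vanishing moments, 8 taps) orthonormal filter pair.
db4_filters <- function() {
  lo <- c(-0.010597401784997278, 0.032883011666982945, 0.030841381835986965,
          -0.18703481171888114, -0.02798376941698385, 0.6308807679295904,
          0.7148465705525415, 0.23037781330885523)
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo, hi = hi)
}

# Half-sample symmetric extension index (0-based in, 1-based out).
reflect_index <- function(i, n) {
  j <- i %% (2L * n)
  j[j < 0] <- j[j < 0] + 2L * n
  j[j >= n] <- 2L * n - 1L - j[j >= n]
  j + 1L
}

# One analysis step: convolve with the filter pair under symmetric extension
# and downsample by two. Returns approximation and detail coefficients.
dwt_step <- function(x, filters) {
  n <- length(x)
  flen <- length(filters$lo)
  n_out <- ceiling(n / 2)
  pos <- 2L * (seq_len(n_out) - 1L)            # 0-based start per output
  idx <- outer(pos, seq_len(flen) - 1L, function(p, j) p + j - (flen %/% 2L - 1L))
  xe <- matrix(x[reflect_index(idx, n)], n_out, flen)
  list(approx = as.numeric(xe %*% rev(filters$lo)),
       detail = as.numeric(xe %*% rev(filters$hi)))
}

#' Multi-level discrete wavelet decomposition
#'
#' Decimated DWT with a Daubechies-4 (8-tap) orthonormal filter bank and
#' half-sample symmetric boundary extension.
#'
#' @param x Numeric series.
#' @param levels Number of decomposition levels; 9 by default.
#' @return List with `details` (list of detail-coefficient vectors, level 1 =
#'   finest) and `approx` (coarsest approximation).
#' @export
dwt_multilevel <- function(x, levels = 9) {
  filters <- db4_filters()
  details <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    if (length(a) < 2) {
      details[[lev]] <- 0
      next
    }
    st <- dwt_step(a, filters)
    details[[lev]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

# The seven summary statistics shared by all wavelet bands. Kurtosis is
# excess kurtosis; skew and kurtosis of a constant series are defined as 0.
band_stats <- function(x, fs) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-24) {
    skew <- 0
    kurt <- 0
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  }
  psd <- welch_psd(x, fs)
  c(rms = sqrt(mean(x^2)), sd = sqrt(m2), max = max(x),
    kurtosis = kurt, skew = skew,
    psd_max = max(psd$density), psd_min = min(psd$density))
}

#' Extract the 70 wavelet-derived features from one window
#'
#' Computes the acceleration magnitude from the three axes, decomposes it
#' over nine wavelet levels, and reports seven statistics (RMS, standard
#' deviation, maximum, kurtosis, skew, PSD maximum, PSD minimum) for the
#' original magnitude series and for each level's detail coefficients:
#' 7 x (1 + 9) = 70 features in a fixed order (signal-major:
#' `orig_*`, `d1_*`, ..., `d9_*`).
#'
#' @param window 3 x L acceleration matrix, or a window list with an `acc`
#'   field.
#' @param fs_hz Sampling frequency (detail level j is treated as sampled at
#'   `fs_hz / 2^j` for its PSD).
#' @param levels Decomposition levels; 9 by default.
#' @return Named numeric vector of length `7 * (levels + 1)`.
#' @export
extract_features <- function(window, fs_hz = 50, levels = 9) {
  acc <- if (is.list(window)) window$acc else window
  stopifnot(is.matrix(acc), nrow(acc) == 3, ncol(acc) >= 2)
  mag <- sqrt(colSums(acc^2))
  dec <- dwt_multilevel(mag, levels = levels)
  stats_list <- vector("list", levels + 1)
  stats_list[[1]] <- band_stats(mag, fs_hz)
  names(stats_list)[1] <- "orig"
  for (j in seq_len(levels)) {
    d <- dec$details[[j]]
    if (length(d) < 2) d <- c(d, 0)
    stats_list[[j + 1]] <- band_stats(d, fs_hz / 2^j)
    names(stats_list)[j + 1] <- paste0("d", j)
  }
  out <- unlist(stats_list)
  names(out) <- unlist(lapply(names(stats_list), function(nm) {
    paste0(nm, "_", c("rms", "sd", "max", "kurtosis", "skew",
                      "psd_max", "psd_min"))
  }))
  out
}

#' Feature matrix for a whole windowed dataset
#'
#' @param dataset A `windowed_dataset`.
#' @param levels Decomposition levels.
#' @return N x 70 matrix with named columns.
#' @export
extract_feature_matrix <- function(dataset, levels = 9) {
  n <- dim(dataset$X)[1]
  first <- extract_features(matrix(dataset$X[1, , ], 3), dataset$fs_hz, levels)
  out <- matrix(0, n, length(first), dimnames = list(NULL, names(first)))
  out[1, ] <- first
  if (n > 1) {
    for (i in 2:n) {
      out[i, ] <- extract_features(matrix(dataset$X[i, , ], 3),
                                   dataset$fs_hz, levels)
    }
  }
  out
}

#' Write a feature matrix as CSV
#'
#' @param features Matrix from [extract_feature_matrix()].
#' @param path Output file.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}

#' Configuration for the baseline multi-layer perceptron
#'
#' @param hidden Hidden-layer widths; two layers of 128 sigmoid units by
#'   default.
#' @param max_epochs,lr,batch_size Adam training parameters.
#' @param seed Integer seed.
#' @return Object of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(128, 128), max_epochs = 200, lr = 1e-3,
                       batch_size = 64, seed = 1L) {
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "mlp_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(params, X) {
  # X: N x P standardized features
  acts <- list()
  A <- X
  n_hidden <- length(params$W) - 1L
  for (i in seq_len(n_hidden)) {
    Z <- A %*% params$W[[i]] +
      matrix(params$b[[i]], nrow(A), length(params$b[[i]]), byrow = TRUE)
    A_new <- sigmoid(Z)
    acts[[i]] <- list(A_in = A, A_out = A_new)
    A <- A_new
  }
  logits <- A %*% params$W[[n_hidden + 1L]] +
    matrix(params$b[[n_hidden + 1L]], nrow(A),
           length(params$b[[n_hidden + 1L]]), byrow = TRUE)
  list(proba = softmax(logits), acts = acts, A_last = A)
}

mlp_backward <- function(params, fw, y_index) {
  n_hidden <- length(params$W) - 1L
  dLogits <- softmax_ce_grad(fw$proba, y_index)
  gW <- vector("list", n_hidden + 1L)
  gb <- vector("list", n_hidden + 1L)
  gW[[n_hidden + 1L]] <- crossprod(fw$A_last, dLogits)
  gb[[n_hidden + 1L]] <- colSums(dLogits)
  dA <- dLogits %*% t(params$W[[n_hidden + 1L]])
  for (i in rev(seq_len(n_hidden))) {
    act <- fw$acts[[i]]
    dZ <- dA * act$A_out * (1 - act$A_out)
    gW[[i]] <- crossprod(act$A_in, dZ)
    gb[[i]] <- colSums(dZ)
    dA <- dZ %*% t(params$W[[i]])
  }
  list(W = gW, b = gb)
}

#' Fit the baseline MLP on explicit features
#'
#' Standardizes features (training statistics only) and trains a fully
#' connected network with sigmoid hidden activations and a softmax output by
#' minimizing mean categorical cross-entropy with Adam.
#'
#' @param features N x P feature matrix.
#' @param labels Integer class indices (1-based).
#' @param config An [mlp_config()].
#' @param class_names Optional class names.
#' @return Object of class `mlp_model`.
#' @export
fit_mlp <- function(features, labels, config = mlp_config(),
                    class_names = NULL) {
  y <- as.integer(labels)
  class_names <- class_names %||% as.character(sort(unique(y)))
  n_classes <- length(class_names)
  if (length(unique(y)) < 2) stop("need at least 2 classes to fit the MLP")
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  widths <- c(ncol(Xs), config$hidden, n_classes)
  with_seed(config$seed, {
    params <- list(W = vector("list", length(widths) - 1L),
                   b = vector("list", length(widths) - 1L))
    for (i in seq_len(length(widths) - 1L)) {
      params$W[[i]] <- matrix(stats::rnorm(widths[i] * widths[i + 1L],
                                           sd = sqrt(1 / widths[i])),
                              widths[i], widths[i + 1L])
      params$b[[i]] <- rep(0, widths[i + 1L])
    }
    state <- adam_init(params)
    n <- nrow(Xs)
    losses <- numeric(config$max_epochs)
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(n)
      bl <- c()
      for (b0 in seq(1, n, by = config$batch_size)) {
        idx <- ord[b0:min(b0 + config$batch_size - 1, n)]
        fw <- mlp_forward(params, Xs[idx, , drop = FALSE])
        loss <- cross_entropy(fw$proba, y[idx])
        if (!is.finite(loss)) stop("non-finite MLP loss at epoch ", ep)
        bl <- c(bl, loss)
        grads <- mlp_backward(params, fw, y[idx])
        upd <- adam_step(params, grads, state, lr = config$lr)
        params <- upd$params
        state <- upd$state
      }
      losses[ep] <- mean(bl)
    }
    structure(list(params = params, center = center, scale = scale,
                   class_names = class_names, config = config,
                   loss_trajectory = losses, hidden = config$hidden),
              class = "mlp_model")
  })
}

#' @rdname fit_mlp
#' @param object An `mlp_model`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param y_true Optional ground-truth labels to attach.
#' @param ... Unused.
#' @export
predict.mlp_model <- function(object, newdata, y_true = NULL, ...) {
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  fw <- mlp_forward(object$params, Xs)
  prediction_set(y_true = y_true, scores = fw$proba,
                 class_names = object$class_names, proba = TRUE)
}

#' Train the wavelet-feature MLP pipeline on a windowed dataset
#'
#' @param dataset A `windowed_dataset`.
#' @param config An [mlp_config()].
#' @return Object of class `wavelet_mlp_pipeline`.
#' @export
wavelet_mlp_train <- function(dataset, config = mlp_config()) {
  feats <- extract_feature_matrix(dataset)
  model <- fit_mlp(feats, dataset$label, config,
                   class_names = dataset$class_names)
  structure(list(model = model, class_names = dataset$class_names),
            class = "wavelet_mlp_pipeline")
}

#' @rdname wavelet_mlp_train
#' @param object A `wavelet_mlp_pipeline`.
#' @param newdata A `windowed_dataset`.
#' @param ... Unused.
#' @export
predict.wavelet_mlp_pipeline <- function(object, newdata, ...) {
  feats <- extract_feature_matrix(newdata)
  predict(object$model, feats, y_true = newdata$label)
}
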