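#' Configuration for the Inception-style time-series network
#'
#' Defaults follow the architecture the method's published results rely on:
#' six stacked Inception modules, longest filter 40 samples, 32 filters per
#' branch, a 32-channel bottleneck, residual shortcuts, batch size 64 and up
#' to 600 training epochs.
#'
#' @param depth Number of stacked Inception modules.
#' @param filter_size Length of the longest convolution filter; the two
#'   other branches use `filter_size / 2` and `filter_size / 4` (integer
#'   division, minimum 2).
#' @param n_filters Filters per convolution branch (standard mode), or the
#'   number of halving-length single-filter branches in
#'   `branch_mode = "halving_count"`.
#' @param bottleneck_channels Channels of the 1x1 input bottleneck; set 1
#'   for a strictly univariate bottleneck.
#' @param residual Add a projected shortcut every third module (the final
#'   module is always connected).
#' @param batch_size,max_epochs,lr Training parameters (Adam step size
#'   `lr`).
#' @param n_classes,n_channels Output classes and input channels.
#' @param branch_mode `"standard"` (3 branches of halving length, each with
#'   `n_filters` filters) or `"halving_count"` (`n_filters` branches of
#'   halving length, one filter each).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return Object of class `inception_config`.
#' @export
inception_config <- function(depth = 6, filter_size = 40, n_filters = 32,
                             bottleneck_channels = 32, residual = TRUE,
                             batch_size = 64, max_epochs = 600, lr = 1e-3,
                             n_classes = 2, n_channels = 3,
                             branch_mode = c("standard", "halving_count"),
                             seed = 1L) {
  stopifnot(depth >= 1, filter_size >= 2, n_filters >= 1)
  structure(list(depth = as.integer(depth),
                 filter_size = as.integer(filter_size),
                 n_filters = as.integer(n_filters),
                 bottleneck_channels = as.integer(bottleneck_channels),
                 residual = isTRUE(residual),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 branch_mode = match.arg(branch_mode),
                 seed = as.integer(seed)),
            class = "inception_config")
}

# Branch filter lengths and filters-per-branch for a config.
branch_spec <- function(config) {
  if (config$branch_mode == "standard") {
    list(lengths = pmax(2L, config$filter_size %/% c(1L, 2L, 4L)),
         per_branch = config$n_filters)
  } else {
    list(lengths = pmax(2L, config$filter_size %/% (2L^(0:(config$n_filters - 1L)))),
         per_branch = 1L)
  }
}

conv_init <- function(l, c_in, n_f) {
  array(stats::rnorm(l * c_in * n_f, sd = sqrt(2 / (l * c_in))),
        dim = c(l, c_in, n_f))
}

# One Inception module's parameters for a given input channel count.
module_init <- function(c_in, config) {
  bs <- branch_spec(config)
  use_bottleneck <- c_in > 1 && config$bottleneck_channels > 0
  b_ch <- if (use_bottleneck) config$bottleneck_channels else c_in
  branches <- lapply(bs$lengths, function(l) conv_init(l, b_ch, bs$per_branch))
  pool_conv <- conv_init(1L, c_in, bs$per_branch)
  c_out <- length(branches) * bs$per_branch + bs$per_branch
  list(bottleneck = if (use_bottleneck) conv_init(1L, c_in, b_ch),
       branches = branches, pool_conv = pool_conv, bn = bn_init(c_out),
       c_in = c_in, c_out = c_out)
}

# Forward one module on (L, C, N); returns pre-activation (before the
# residual add / ReLU, which the network applies) plus caches.
module_forward <- function(X, mod, train = TRUE) {
  caches <- list()
  Z <- X
  if (!is.null(mod$bottleneck)) {
    cf <- conv1d_forward(X, mod$bottleneck)
    Z <- cf$out
    caches$bottleneck <- cf$cache
  }
  branch_outs <- vector("list", length(mod$branches))
  caches$branches <- vector("list", length(mod$branches))
  for (i in seq_along(mod$branches)) {
    cf <- conv1d_forward(Z, mod$branches[[i]])
    branch_outs[[i]] <- cf$out
    caches$branches[[i]] <- cf$cache
  }
  mp <- maxpool1d_forward(X, 3L)
  caches$pool <- mp$cache
  pf <- conv1d_forward(mp$out, mod$pool_conv)
  caches$pool_conv <- pf$cache
  branch_outs <- c(branch_outs, list(pf$out))
  L <- dim(X)[1]; N <- dim(X)[3]
  widths <- vapply(branch_outs, function(b) dim(b)[2], 0L)
  concat <- array(0, dim = c(L, sum(widths), N))
  at <- 0L
  for (b in branch_outs) {
    w <- dim(b)[2]
    concat[, at + seq_len(w), ] <- b
    at <- at + w
  }
  caches$widths <- widths
  bf <- bn_forward(concat, mod$bn, train = train)
  caches$bn <- bf$cache
  list(out = bf$out, mod_bn = bf$bn, caches = caches)
}

module_backward <- function(dY, mod, caches) {
  bnb <- bn_backward(dY, caches$bn)
  grads <- list(bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
  dConcat <- bnb$dX
  widths <- caches$widths
  at <- 0L
  dBranch <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    dBranch[[i]] <- dConcat[, at + seq_len(widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  # pool branch (last)
  pb <- conv1d_backward(dBranch[[length(dBranch)]], mod$pool_conv,
                        caches$pool_conv)
  grads$pool_conv <- pb$dW
  dX <- maxpool1d_backward(pb$dX, caches$pool)
  # convolution branches feed from the bottleneck output Z
  dZ <- NULL
  grads$branches <- vector("list", length(mod$branches))
  for (i in seq_along(mod$branches)) {
    cb <- conv1d_backward(dBranch[[i]], mod$branches[[i]], caches$branches[[i]])
    grads$branches[[i]] <- cb$dW
    dZ <- if (is.null(dZ)) cb$dX else dZ + cb$dX
  }
  if (!is.null(mod$bottleneck)) {
    bb <- conv1d_backward(dZ, mod$bottleneck, caches$bottleneck)
    grads$bottleneck <- bb$dW
    dX <- dX + bb$dX
  } else {
    dX <- dX + dZ
  }
  list(dX = dX, grads = grads)
}

#' Apply one randomly initialized Inception module to a multivariate series
#'
#' Builds a single module for the input's channel count and returns the
#' transformed multivariate series. The module concatenates three (or
#' `n_filters`, see `branch_mode`) convolution branches fed by a 1x1
#' bottleneck with a max-pool + bottleneck branch, then batch-normalizes and
#' applies ReLU; the output length always equals the input length.
#'
#' @param input A channels x length matrix (an MTS).
#' @param config An [inception_config()].
#' @return A channels_out x length matrix.
#' @export
inception_module <- function(input, config = inception_config()) {
  stopifnot(is.matrix(input), nrow(input) >= 1)
  X <- array(t(input), dim = c(ncol(input), nrow(input), 1L))
  mod <- with_seed(config$seed, module_init(nrow(input), config))
  fw <- module_forward(X, mod, train = TRUE)
  out <- pmax(fw$out[, , 1, drop = FALSE], 0)
  t(matrix(out, dim(fw$out)[1], dim(fw$out)[2]))
}

# Per-window, per-channel centering of an (L, C, N) batch: removes the
# static gravity component while preserving motion amplitude (the network's
# own input normalization; amplitude carries the bradykinesia signature).
center_windows <- function(X) {
  mu <- apply(X, c(2, 3), mean)
  X - aperm(array(mu, dim = c(dim(X)[2], dim(X)[3], dim(X)[1])), c(3, 1, 2))
}

# Indices of modules carrying a residual shortcut.
residual_positions <- function(config) {
  if (!config$residual) return(integer(0))
  pos <- seq_len(config$depth)[seq_len(config$depth) %% 3L == 0L]
  sort(unique(c(pos, config$depth)))
}

#' Build an untrained Inception network
#'
#' Stacks `depth` Inception modules (with projected residual shortcuts every
#' third module and at the final module when `residual`), global average
#' pooling over time, and a fully connected softmax output layer.
#'
#' @param config An [inception_config()].
#' @return Object of class `inception_model` (untrained).
#' @export
build_network <- function(config) {
  with_seed(config$seed, {
    res_pos <- residual_positions(config)
    modules <- vector("list", config$depth)
    shortcuts <- vector("list", config$depth)
    c_in <- config$n_channels
    c_res <- config$n_channels
    for (m in seq_len(config$depth)) {
      modules[[m]] <- module_init(c_in, config)
      c_out <- modules[[m]]$c_out
      if (m %in% res_pos) {
        shortcuts[[m]] <- list(W = conv_init(1L, c_res, c_out),
                               bn = bn_init(c_out))
        c_res <- c_out
      }
      c_in <- c_out
    }
    fc <- list(W = matrix(stats::rnorm(c_in * config$n_classes,
                                       sd = sqrt(2 / c_in)),
                          c_in, config$n_classes),
               b = rep(0, config$n_classes))
    structure(list(modules = modules, shortcuts = shortcuts, fc = fc,
                   config = config, res_pos = res_pos, trained = FALSE,
                   loss_trajectory = numeric(0)),
              class = "inception_model")
  })
}

#' Count trainable parameters of an Inception network
#'
#' @param model An `inception_model`.
#' @return Integer parameter count (convolutions, batch-norm scale/shift,
#'   shortcut projections, dense layer).
#' @export
parameter_count <- function(model) {
  n <- 0
  for (mod in model$modules) {
    if (!is.null(mod$bottleneck)) n <- n + length(mod$bottleneck)
    for (b in mod$branches) n <- n + length(b)
    n <- n + length(mod$pool_conv) + length(mod$bn$gamma) + length(mod$bn$beta)
  }
  for (s in model$shortcuts) {
    if (!is.null(s)) n <- n + length(s$W) + length(s$bn$gamma) + length(s$bn$beta)
  }
  n + length(model$fc$W) + length(model$fc$b)
}

# Full forward pass. X: (L, C, N). Returns probabilities and caches.
network_forward <- function(model, X, train = TRUE) {
  cfg <- model$config
  caches <- vector("list", cfg$depth)
  relu_caches <- vector("list", cfg$depth)
  shortcut_caches <- vector("list", cfg$depth)
  res_origin <- integer(cfg$depth)  # module index whose output is res input
  h <- X
  res_in <- X
  origin <- 0L
  for (m in seq_len(cfg$depth)) {
    fw <- module_forward(h, model$modules[[m]], train = train)
    model$modules[[m]]$bn <- fw$mod_bn
    pre <- fw$out
    caches[[m]] <- fw$caches
    res_origin[m] <- origin
    if (!is.null(model$shortcuts[[m]])) {
      sc <- model$shortcuts[[m]]
      cf <- conv1d_forward(res_in, sc$W)
      bf <- bn_forward(cf$out, sc$bn, train = train)
      model$shortcuts[[m]]$bn <- bf$bn
      shortcut_caches[[m]] <- list(conv = cf$cache, bn = bf$cache)
      pre <- pre + bf$out
    }
    rl <- relu_forward(pre)
    relu_caches[[m]] <- rl$cache
    h <- rl$out
    if (!is.null(model$shortcuts[[m]])) {
      res_in <- h
      origin <- m
    }
  }
  L <- dim(h)[1]
  A <- apply(h, c(2, 3), mean)                  # (C, N) global average pool
  if (is.null(dim(A))) A <- matrix(A, nrow = 1)
  df <- dense_forward(A, model$fc$W, model$fc$b)
  proba <- softmax(df$out)
  list(proba = proba, model = model,
       caches = list(modules = caches, relu = relu_caches,
                     shortcuts = shortcut_caches, res_origin = res_origin,
                     dense = df$cache, L = L, dimX = dim(X)))
}

network_backward <- function(model, caches, proba, y_index) {
  cfg <- model$config
  dLogits <- softmax_ce_grad(proba, y_index)
  db <- dense_backward(dLogits, model$fc$W, caches$dense)
  grads <- list(fc = list(W = db$dW, b = db$db),
                modules = vector("list", cfg$depth),
                shortcuts = vector("list", cfg$depth))
  L <- caches$L
  dA <- db$dA                                    # (C, N)
  dh <- array(rep(as.numeric(dA) / L, each = L),
              dim = c(L, nrow(dA), ncol(dA)))
  pending <- vector("list", cfg$depth + 1L)      # grads addressed to outputs
  for (m in rev(seq_len(cfg$depth))) {
    extra <- pending[[m + 1L]]
    if (!is.null(extra)) dh <- dh + extra
    dPre <- relu_backward(dh, caches$relu[[m]])
    if (!is.null(model$shortcuts[[m]])) {
      sc <- model$shortcuts[[m]]
      scc <- caches$shortcuts[[m]]
      bnb <- bn_backward(dPre, scc$bn)
      cb <- conv1d_backward(bnb$dX, sc$W, scc$conv)
      grads$shortcuts[[m]] <- list(W = cb$dW,
                                   bn = list(gamma = bnb$dgamma,
                                             beta = bnb$dbeta))
      tgt <- caches$res_origin[m] + 1L
      pending[[tgt]] <- if (is.null(pending[[tgt]])) cb$dX else
        pending[[tgt]] + cb$dX
    }
    mb <- module_backward(dPre, model$modules[[m]], caches$modules[[m]])
    grads$modules[[m]] <- mb$grads
    dh <- mb$dX
  }
  dX <- dh
  if (!is.null(pending[[1L]])) dX <- dX + pending[[1L]]
  list(grads = grads, dX = dX)
}

# Trainable parameters / matching gradient trees for Adam.
network_params <- function(model) {
  list(fc = model$fc,
       modules = lapply(model$modules, function(m) {
         keep <- list(branches = m$branches, pool_conv = m$pool_conv,
                      bn = list(gamma = m$bn$gamma, beta = m$bn$beta))
         if (!is.null(m$bottleneck)) keep$bottleneck <- m$bottleneck
         keep
       }),
       shortcuts = lapply(model$shortcuts, function(s) {
         if (is.null(s)) NULL else
           list(W = s$W, bn = list(gamma = s$bn$gamma, beta = s$bn$beta))
       }))
}

network_set_params <- function(model, params) {
  model$fc <- params$fc
  for (m in seq_along(model$modules)) {
    p <- params$modules[[m]]
    model$modules[[m]]$branches <- p$branches
    model$modules[[m]]$pool_conv <- p$pool_conv
    model$modules[[m]]$bn$gamma <- p$bn$gamma
    model$modules[[m]]$bn$beta <- p$bn$beta
    if (!is.null(p$bottleneck)) model$modules[[m]]$bottleneck <- p$bottleneck
    s <- params$shortcuts[[m]]
    if (!is.null(s)) {
      model$shortcuts[[m]]$W <- s$W
      model$shortcuts[[m]]$bn$gamma <- s$bn$gamma
      model$shortcuts[[m]]$bn$beta <- s$bn$beta
    }
  }
  model
}

#' Train an Inception network
#'
#' Each window is centered per channel first (the network's input
#' normalization: it removes the orientation-dependent gravity offset while
#' preserving motion amplitude). Training minimizes mean categorical
#' cross-entropy with Adam (step size
#' `config$lr`, batch size `config$batch_size`) for up to
#' `config$max_epochs` epochs. Deterministic given the config seed under
#' single-threaded execution. Aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param model An `inception_model` from [build_network()].
#' @param dataset A `windowed_dataset` whose windows match the config's
#'   channel count.
#' @param epochs Optional override of `config$max_epochs` (desk-scale runs).
#' @param verbose Print the loss every 10 epochs.
#' @return The trained `inception_model` with `loss_trajectory` filled in.
#' @export
inception_train <- function(model, dataset, epochs = NULL, verbose = FALSE) {
  cfg <- model$config
  X <- center_windows(aperm(dataset$X, c(3, 2, 1)))   # (L, C, N)
  y <- dataset$label
  stopifnot(dim(X)[2] == cfg$n_channels)
  n <- dim(X)[3]
  n_epochs <- epochs %||% cfg$max_epochs
  with_seed(cfg$seed + 1L, {
    params <- network_params(model)
    state <- adam_init(params)
    losses <- numeric(n_epochs)
    for (ep in seq_len(n_epochs)) {
      ord <- sample(n)
      batch_losses <- c()
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        Xb <- X[, , idx, drop = FALSE]
        fw <- network_forward(model, Xb, train = TRUE)
        model <- fw$model
        loss <- cross_entropy(fw$proba, y[idx])
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", ep,
               "; inspect learning rate and input scaling")
        }
        batch_losses <- c(batch_losses, loss)
        bw <- network_backward(model, fw$caches, fw$proba, y[idx])
        upd <- adam_step(params, bw$grads, state, lr = cfg$lr)
        params <- upd$params
        state <- upd$state
        model <- network_set_params(model, params)
      }
      losses[ep] <- mean(batch_losses)
      if (verbose && ep %% 10 == 0) {
        message("epoch ", ep, " loss ", signif(losses[ep], 4))
      }
    }
    model$loss_trajectory <- losses
    model$trained <- TRUE
    model
  })
}

#' Predict with a (trained) Inception network
#'
#' @param object An `inception_model`.
#' @param newdata A `windowed_dataset`.
#' @param ... Unused.
#' @return A [prediction_set()].
#' @export
predict.inception_model <- function(object, newdata, ...) {
  X <- center_windows(aperm(newdata$X, c(3, 2, 1)))
  fw <- network_forward(object, X, train = FALSE)
  prediction_set(y_true = newdata$label, scores = fw$proba,
                 class_names = newdata$class_names, proba = TRUE)
}

#' Ensemble prediction from five Inception networks
#'
#' The ensemble prediction is the arithmetic mean of the member networks'
#' probability vectors (rows still sum to 1 by convexity). Members must share
#' the class count; they differ only by random initialization seed.
#'
#' @param models List of trained `inception_model`s (five in the reference
#'   configuration).
#' @param dataset A `windowed_dataset`.
#' @return A [prediction_set()].
#' @export
ensemble_predict <- function(models, dataset) {
  ks <- vapply(models, function(m) m$config$n_classes, 0L)
  if (length(unique(ks)) != 1) {
    stop("ensemble members disagree on the number of classes")
  }
  probs <- lapply(models, function(m) predict(m, dataset)$scores)
  avg <- Reduce(`+`, probs) / length(probs)
  prediction_set(y_true = dataset$label, scores = avg,
                 class_names = dataset$class_names, proba = TRUE)
}
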