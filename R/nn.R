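# Minimal neural-network primitives on (L, C, N) arrays (time, channel,
# batch), written against BLAS matmul via im2col. Used by the Inception
# network and the feature MLP. All layers return forward caches consumed by
# the matching backward pass; gradients are exact (finite-difference checked
# in the test suite).

# ---- 1D convolution, stride 1, 'same' zero padding, no bias ----

conv1d_forward <- function(X, W) {
  ld <- dim(X)  # (L, C, N)
  L <- ld[1]; C <- ld[2]; N <- ld[3]
  l <- dim(W)[1]; F <- dim(W)[3]
  pad_l <- (l - 1L) %/% 2L
  Xp <- array(0, dim = c(L + l - 1L, C, N))
  Xp[pad_l + seq_len(L), , ] <- X
  Xcol <- matrix(0, L * N, l * C)
  for (j in seq_len(l)) {
    slice <- Xp[j + 0:(L - 1L), , , drop = FALSE]      # (L, C, N)
    Xcol[, (j - 1L) * C + seq_len(C)] <-
      matrix(aperm(slice, c(1, 3, 2)), L * N, C)
  }
  Wmat <- matrix(aperm(W, c(2, 1, 3)), C * l, F)
  Y <- Xcol %*% Wmat                                   # (L*N, F)
  out <- aperm(array(Y, dim = c(L, N, F)), c(1, 3, 2)) # (L, F, N)
  list(out = out, cache = list(Xcol = Xcol, dimX = ld, l = l, F = F,
                               pad_l = pad_l))
}

conv1d_backward <- function(dY, W, cache) {
  L <- cache$dimX[1]; C <- cache$dimX[2]; N <- cache$dimX[3]
  l <- cache$l; F <- cache$F; pad_l <- cache$pad_l
  dYmat <- matrix(aperm(dY, c(1, 3, 2)), L * N, F)
  Wmat <- matrix(aperm(W, c(2, 1, 3)), C * l, F)
  dWmat <- crossprod(cache$Xcol, dYmat)                # (C*l, F)
  dW <- aperm(array(dWmat, dim = c(C, l, F)), c(2, 1, 3))
  dXcol <- dYmat %*% t(Wmat)                           # (L*N, C*l)
  dXp <- array(0, dim = c(L + l - 1L, C, N))
  for (j in seq_len(l)) {
    block <- array(dXcol[, (j - 1L) * C + seq_len(C)], dim = c(L, N, C))
    dXp[j + 0:(L - 1L), , ] <- dXp[j + 0:(L - 1L), , ] + aperm(block, c(1, 3, 2))
  }
  list(dX = dXp[pad_l + seq_len(L), , , drop = FALSE], dW = dW)
}

# ---- max pooling, window k, stride 1, 'same' length ----

maxpool1d_forward <- function(X, k = 3L) {
  ld <- dim(X); L <- ld[1]
  pad_l <- (k - 1L) %/% 2L
  Xp <- array(-Inf, dim = c(L + k - 1L, ld[2], ld[3]))
  Xp[pad_l + seq_len(L), , ] <- X
  out <- array(-Inf, dim = ld)
  arg <- array(1L, dim = ld)
  for (j in seq_len(k)) {
    cand <- Xp[j + 0:(L - 1L), , , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(out = out, cache = list(arg = arg, k = k, pad_l = pad_l, dimX = ld))
}

maxpool1d_backward <- function(dY, cache) {
  ld <- cache$dimX; L <- ld[1]
  dXp <- array(0, dim = c(L + cache$k - 1L, ld[2], ld[3]))
  for (j in seq_len(cache$k)) {
    mask <- cache$arg == j
    add <- array(0, dim = ld)
    add[mask] <- dY[mask]
    dXp[j + 0:(L - 1L), , ] <- dXp[j + 0:(L - 1L), , ] + add
  }
  dXp[cache$pad_l + seq_len(L), , , drop = FALSE]
}

# ---- batch normalization over (time, batch) per channel ----

bn_init <- function(C) {
  list(gamma = rep(1, C), beta = rep(0, C),
       run_mean = rep(0, C), run_var = rep(1, C))
}

bn_forward <- function(X, bn, train = TRUE, momentum = 0.9, eps = 1e-5) {
  C <- dim(X)[2]
  if (train) {
    mu <- apply(X, 2, mean)
    v <- apply(X, 2, function(z) mean((z - mean(z))^2))
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(X, 2, mu), 2, inv_sd, "*")
  out <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  list(out = out, bn = bn,
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = bn$gamma))
}

bn_backward <- function(dY, cache) {
  xhat <- cache$xhat
  M <- dim(dY)[1] * dim(dY)[3]
  dgamma <- apply(dY * xhat, 2, sum)
  dbeta <- apply(dY, 2, sum)
  mean_dy <- dbeta / M
  mean_dyx <- dgamma / M
  # dX = gamma * inv_sd * (dY - mean(dY) - xhat * mean(dY * xhat))
  term <- sweep(dY, 2, mean_dy) - sweep(xhat, 2, mean_dyx, "*")
  dX <- sweep(term, 2, cache$gamma * cache$inv_sd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_backward <- function(dY, cache) dY * cache

# ---- dense head on (C, N) features ----

dense_forward <- function(A, W, b) {
  # A: (P, N) features; W: (P, K); b: length K
  out <- t(A) %*% W + matrix(b, ncol(A), length(b), byrow = TRUE)  # (N, K)
  list(out = out, cache = A)
}

dense_backward <- function(dY, W, cache) {
  list(dA = W %*% t(dY),                 # (P, N)
       dW = cache %*% dY,                # (P, K)
       db = colSums(dY))
}

#' Softmax over rows
#'
#' Maps a matrix (or vector) of class likelihoods to probabilities with the
#' usual max-subtraction for numerical stability; each row sums to 1 and is
#' invariant to adding a constant to all likelihoods of that row.
#'
#' @param x Numeric vector or N x K matrix of finite likelihoods.
#' @return Object of the same shape with rows summing to 1.
#' @export
softmax <- function(x) {
  if (is.null(dim(x))) {
    z <- exp(x - max(x))
    return(z / sum(z))
  }
  z <- exp(x - apply(x, 1, max))
  z / rowSums(z)
}

# Mean categorical cross-entropy -sum(y * log yhat) / N and its gradient
# with respect to the pre-softmax logits (yhat - y) / N.
cross_entropy <- function(proba, y_index, eps = 1e-12) {
  n <- nrow(proba)
  -mean(log(pmax(proba[cbind(seq_len(n), y_index)], eps)))
}

softmax_ce_grad <- function(proba, y_index) {
  G <- proba
  G[cbind(seq_len(nrow(proba)), y_index)] <-
    G[cbind(seq_len(nrow(proba)), y_index)] - 1
  G / nrow(proba)
}

# ---- Adam over an arbitrary nested list of numeric arrays ----

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) lapply(p, zero_like) else array(0, dim = dim(p) %||% length(p))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (!is.null(names(p)) && all(names(p) != "")) names(p)
              else seq_along(p)
      for (i in keys) {
        if (is.null(p[[i]]) || is.null(g[[i]])) next
        res <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- res$p; out_m[[i]] <- res$m; out_v[[i]] <- res$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g^2
      mhat <- m2 / (1 - beta1^t)
      vhat <- v2 / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}
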