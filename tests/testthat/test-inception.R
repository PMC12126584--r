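test_that("an Inception module concatenates conv branches and the pool branch", {
  # three single-filter branches + pool branch on a 3-channel MTS -> 4 channels
  cfg <- inception_config(n_filters = 1, filter_size = 8,
                          bottleneck_channels = 2, seed = 1)
  out <- inception_module(matrix(rnorm(3 * 60), 3, 60), cfg)
  expect_equal(dim(out), c(4, 60))
  # default: 3 branches x 32 filters + 32-pool = 128 channels
  mod <- pdmotor:::module_init(3, inception_config())
  expect_equal(mod$c_out, 128)
  # halving-count mode: n_filters branches of one filter each + pool
  cfg_h <- inception_config(n_filters = 4, filter_size = 64,
                            branch_mode = "halving_count", seed = 1)
  bs <- pdmotor:::branch_spec(cfg_h)
  expect_equal(bs$lengths, c(64, 32, 16, 8))
  expect_equal(bs$per_branch, 1)
  # output length equals input length for any L
  for (L in c(17, 40, 101)) {
    o <- inception_module(matrix(rnorm(2 * L), 2, L),
                          inception_config(n_filters = 2, filter_size = 10,
                                           bottleneck_channels = 2))
    expect_equal(ncol(o), L)
  }
})

test_that("network parameter count grows with the filter count", {
  counts <- vapply(c(2, 4, 8), function(nf) {
    cfg <- inception_config(depth = 2, filter_size = 12, n_filters = nf,
                            bottleneck_channels = 4, n_classes = 2,
                            n_channels = 3)
    parameter_count(build_network(cfg))
  }, 0)
  expect_true(all(diff(counts) > 0))
  # depth-6 default stacks six modules
  net <- build_network(inception_config(n_classes = 2, n_channels = 3))
  expect_length(net$modules, 6)
})

test_that("softmax outputs are normalized and the loss has known anchors", {
  ds <- make_sine_dataset(10, L = 60, seed = 2)
  cfg <- inception_config(depth = 1, filter_size = 8, n_filters = 2,
                          bottleneck_channels = 2, n_classes = 2,
                          n_channels = 3, seed = 3)
  net <- build_network(cfg)
  pr <- predict(net, ds)
  expect_equal(rowSums(pr$scores), rep(1, 20), tolerance = 1e-9)
  # perfect prediction: zero loss
  onehot <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(pdmotor:::cross_entropy(onehot, c(1, 2)), 0, tolerance = 1e-10)
  # uniform prediction over 4 classes: ln 4 per sample
  unif <- matrix(0.25, 3, 4)
  expect_equal(pdmotor:::cross_entropy(unif, c(1, 2, 3)), log(4),
               tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- inception_config(depth = 3, filter_size = 6, n_filters = 2,
                          bottleneck_channels = 2, n_classes = 3,
                          n_channels = 2, residual = TRUE, seed = 11)
  net <- build_network(cfg)
  set.seed(2)
  X <- array(rnorm(12 * 2 * 3), dim = c(12, 2, 3))
  y <- c(1L, 2L, 3L)
  np <- pdmotor:::network_params(net)
  fw <- pdmotor:::network_forward(net, X, train = TRUE)
  bw <- pdmotor:::network_backward(fw$model, fw$caches, fw$proba, y)
  loss_at <- function(params) {
    m <- pdmotor:::network_set_params(net, params)
    f <- pdmotor:::network_forward(m, X, train = TRUE)
    pdmotor:::cross_entropy(f$proba, y)
  }
  eps <- 1e-6
  check_leaf <- function(get, set, analytic) {
    v <- get(np)
    set.seed(length(v))
    i <- sample(length(v), 1)
    v1 <- v; v1[i] <- v1[i] + eps
    v2 <- v; v2[i] <- v2[i] - eps
    num <- (loss_at(set(np, v1)) - loss_at(set(np, v2))) / (2 * eps)
    expect_equal(analytic[i], num, tolerance = 1e-4)
  }
  check_leaf(function(p) p$fc$W, function(p, v) {p$fc$W[] <- v; p},
             bw$grads$fc$W)
  check_leaf(function(p) p$modules[[1]]$branches[[1]],
             function(p, v) {p$modules[[1]]$branches[[1]][] <- v; p},
             bw$grads$modules[[1]]$branches[[1]])
  check_leaf(function(p) p$modules[[2]]$bottleneck,
             function(p, v) {p$modules[[2]]$bottleneck[] <- v; p},
             bw$grads$modules[[2]]$bottleneck)
  check_leaf(function(p) p$modules[[3]]$bn$gamma,
             function(p, v) {p$modules[[3]]$bn$gamma <- v; p},
             bw$grads$modules[[3]]$bn$gamma)
  check_leaf(function(p) p$shortcuts[[3]]$W,
             function(p, v) {p$shortcuts[[3]]$W[] <- v; p},
             bw$grads$shortcuts[[3]]$W)
})

test_that("perturbations outside the receptive field leave outputs unchanged", {
  cfg <- inception_config(depth = 1, filter_size = 8, n_filters = 2,
                          bottleneck_channels = 2, n_channels = 1, seed = 6)
  mod <- pdmotor:::module_init(1, cfg)
  L <- 120
  set.seed(1)
  x <- array(rnorm(L), dim = c(L, 1, 1))
  base <- pdmotor:::module_forward(x, mod, train = FALSE)$out
  x2 <- x
  x2[110, 1, 1] <- x2[110, 1, 1] + 100  # far from position 20
  pert <- pdmotor:::module_forward(x2, mod, train = FALSE)$out
  # receptive field of position 20 spans at most +/- (8 + pool) samples
  expect_equal(pert[20, , 1], base[20, , 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pert[110, , 1], base[110, , 1])))
})

test_that("training reduces the loss on an easy discrimination", {
  ds <- make_sine_dataset(16, L = 80, seed = 3, amp = 3)
  cfg <- inception_config(depth = 1, filter_size = 10, n_filters = 2,
                          bottleneck_channels = 2, n_classes = 2,
                          n_channels = 3, batch_size = 16, lr = 3e-3, seed = 4)
  net <- inception_train(build_network(cfg), ds, epochs = 10)
  expect_lt(tail(net$loss_trajectory, 1), net$loss_trajectory[1])
  expect_true(all(is.finite(net$loss_trajectory)))
  # deterministic under the config seed
  net2 <- inception_train(build_network(cfg), ds, epochs = 10)
  expect_identical(net$loss_trajectory, net2$loss_trajectory)
})

test_that("five identical members make the ensemble equal a single model", {
  ds <- make_sine_dataset(8, L = 60, seed = 5)
  cfg <- inception_config(depth = 1, filter_size = 8, n_filters = 2,
                          bottleneck_channels = 2, n_classes = 2,
                          n_channels = 3, seed = 7)
  net <- build_network(cfg)
  single <- predict(net, ds)
  ens <- ensemble_predict(list(net, net, net, net, net), ds)
  expect_equal(ens$scores, single$scores, tolerance = 1e-12)
  expect_equal(rowSums(ens$scores), rep(1, 16), tolerance = 1e-9)
  other <- build_network(inception_config(depth = 1, filter_size = 8,
                                          n_filters = 2,
                                          bottleneck_channels = 2,
                                          n_classes = 3, n_channels = 3))
  expect_error(ensemble_predict(list(net, other), ds), "classes")
})

test_that("ensembling reduces score variability across repeats", {
  tr <- make_sine_dataset(12, L = 60, seed = 20, amp = 1.5)
  te <- make_sine_dataset(12, L = 60, seed = 21, amp = 1.5)
  cfg0 <- inception_config(depth = 1, filter_size = 8, n_filters = 2,
                           bottleneck_channels = 2, n_classes = 2,
                           n_channels = 3, batch_size = 12, lr = 3e-3)
  train_at <- function(seed, epochs = 5) {
    cfg <- cfg0; cfg$seed <- seed
    inception_train(build_network(cfg), tr, epochs = epochs)
  }
  singles <- lapply(1:6, train_at)
  single_ba <- vapply(singles, function(m) balanced_accuracy(predict(m, te)), 0)
  ens_ba <- vapply(1:2, function(g) {
    balanced_accuracy(ensemble_predict(singles[(3 * g - 2):(3 * g)], te))
  }, 0)
  # the spread of ensemble scores cannot exceed the single-model spread
  expect_lte(stats::sd(ens_ba), stats::sd(single_ba) + 1e-9)
})

test_that("the network recovers bradykinesia labels on an easy cohort", {
  co <- generate_cohort(brady_cohort_config(seed = 21))
  ds <- windowed_dataset(co, "bradykinesia", 3, 0.5)
  parts <- split_by_patients(co, ds, "bradykinesia", seed = 2)
  cfg <- inception_config(depth = 2, filter_size = 16, n_filters = 4,
                          bottleneck_channels = 4, n_classes = 2,
                          n_channels = 3, batch_size = 32, lr = 3e-3, seed = 5)
  net <- inception_train(build_network(cfg), parts$train, epochs = 25)
  ba <- balanced_accuracy(predict(net, parts$test))
  expect_gte(ba, 0.85)
  # permuted labels: chance level on the held-out patients
  trp <- parts$train
  set.seed(9)
  trp$label <- sample(trp$label)
  netp <- inception_train(build_network(cfg), trp, epochs = 25)
  bap <- balanced_accuracy(predict(netp, parts$test))
  counts <- table(parts$test$label)
  expect_lt(abs(bap - 0.5), ba_3se(counts[1], counts[2]))
})
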