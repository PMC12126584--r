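# Independent brute-force oracles kept deliberately simple.
ba_oracle <- function(y, yhat) {
  mean(vapply(sort(unique(y)), function(cl) {
    sum(yhat == cl & y == cl) / sum(y == cl)
  }, 0))
}

ap_oracle <- function(scores, pos) {
  ths <- sort(unique(scores), decreasing = TRUE)
  r_prev <- 0; ap <- 0
  for (th in ths) {
    sel <- scores >= th
    p <- sum(pos & sel) / sum(sel)
    r <- sum(pos & sel) / sum(pos)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

auroc_pair_oracle <- function(s_pos, is_pos) {
  pos <- s_pos[is_pos]; neg <- s_pos[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

make_pred <- function(y, K = max(y), seed = 1) {
  set.seed(seed)
  s <- matrix(runif(length(y) * K), length(y), K)
  s <- s / rowSums(s)
  prediction_set(y, s, as.character(seq_len(K)))
}

test_that("balanced accuracy equals the mean per-class recall", {
  p <- prediction_set(c(1, 1, 2, 2, 2),
                      cbind(c(.9, .4, .3, .2, .6), c(.1, .6, .7, .8, .4)),
                      c("a", "b"))
  expect_equal(balanced_accuracy(p), (1 / 2 + 2 / 3) / 2)
  # constant single-class prediction on a binary task: 0.5
  pc <- prediction_set(c(1, 1, 2, 2), cbind(rep(.9, 4), rep(.1, 4)),
                       c("a", "b"))
  expect_equal(balanced_accuracy(pc), 0.5)
  perfect <- prediction_set(1:3, diag(3), c("a", "b", "c"))
  expect_equal(balanced_accuracy(perfect), 1)
  expect_equal(accuracy(perfect), 1)
})

test_that("average precision follows the recall-weighted threshold sum", {
  # perfectly ranked
  p <- prediction_set(c(2, 2, 1, 1),
                      cbind(c(.1, .2, .8, .9), c(.9, .8, .2, .1)),
                      c("n", "p"))
  expect_equal(average_precision(p, "p"), 1)
  # single positive ranked last of two samples
  p2 <- prediction_set(c(1, 2), cbind(c(.2, .9), c(.8, .1)), c("n", "p"))
  expect_equal(average_precision(p2, "p"), 0.5)
  # constant scores collapse to a single threshold: AP = prevalence
  p3 <- prediction_set(c(1, 2, 2), matrix(0.5, 3, 2), c("n", "p"))
  expect_equal(average_precision(p3, "p"), 2 / 3)
  expect_error(average_precision(
    prediction_set(c(1, 1), matrix(0.5, 2, 2), c("n", "p")), "p"),
    "no positive")
})

test_that("AP and BA agree with brute-force oracles on random cases", {
  for (case in 1:50) {
    set.seed(case)
    n <- sample(5:30, 1)
    y <- sample(1:2, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 1:2
    s2 <- runif(n)
    p <- prediction_set(y, cbind(1 - s2, s2), c("n", "p"))
    expect_equal(average_precision(p, 2), ap_oracle(s2, y == 2),
                 tolerance = 1e-12)
    expect_equal(balanced_accuracy(p), ba_oracle(y, p$y_pred),
                 tolerance = 1e-12)
  }
})

test_that("macro F1 averages one-vs-rest F1 with stated conventions", {
  perfect <- prediction_set(1:3, diag(3), c("a", "b", "c"))
  expect_equal(f1_macro(perfect), 1)
  # class with P = R = 0.5 contributes F1 = 0.5
  p <- prediction_set(c(1, 1, 2, 2),
                      cbind(c(.9, .1, .9, .1), c(.1, .9, .1, .9)),
                      c("a", "b"))
  expect_equal(f1_macro(p), 0.5)
  # absent predictions and absent positives: class F1 = 0 by convention
  p2 <- prediction_set(c(1, 1), cbind(c(.9, .8), c(.1, .2)), c("a", "b"))
  expect_equal(f1_macro(p2), (1 + 0) / 2)
})

test_that("one-vs-one AUROC equals the pairwise enumeration oracle", {
  sep <- prediction_set(c(1, 1, 2, 2),
                        cbind(c(.9, .8, .2, .1), c(.1, .2, .8, .9)),
                        c("n", "p"))
  expect_equal(auroc(sep), 1)
  for (case in 1:10) {
    set.seed(case + 100)
    n <- 50
    y <- sample(1:3, n, replace = TRUE)
    y[1:3] <- 1:3
    s <- matrix(runif(n * 3), n, 3)
    s <- s / rowSums(s)
    p <- prediction_set(y, s, c("a", "b", "c"))
    pairs <- combn(3, 2)
    oracle <- mean(apply(pairs, 2, function(pr) {
      i <- pr[1]; j <- pr[2]
      sel <- y %in% c(i, j)
      (auroc_pair_oracle(s[sel, i], y[sel] == i) +
         auroc_pair_oracle(s[sel, j], y[sel] == j)) / 2
    }))
    expect_equal(auroc(p), oracle, tolerance = 1e-12)
  }
  # random scores on a balanced binary task: 0.5 within Monte-Carlo error
  set.seed(7)
  n <- 10000
  y <- rep(1:2, n / 2)
  s2 <- runif(n)
  p <- prediction_set(y, cbind(1 - s2, s2), c("n", "p"))
  expect_lt(abs(auroc(p) - 0.5), 3 / sqrt(n))
})

test_that("MAMAE macro-averages per-class absolute errors", {
  perfect <- prediction_set(1:3, diag(3), c("0", "1", "2"))
  expect_equal(mamae(perfect), 0)
  # y = (0,0,2), yhat = (2,0,2): class MAEs 1 and 0
  p <- prediction_set(c(1, 1, 3),
                      rbind(c(.1, .2, .7), c(.8, .1, .1), c(.1, .2, .7)),
                      c("0", "1", "2"))
  expect_equal(mamae(p), 0.5)
  # always predicting class 0 with all four classes present: mean(0,1,2,3)
  p2 <- prediction_set(rep(1:4, each = 2),
                       matrix(rep(c(.7, .1, .1, .1), 8), 8, 4, byrow = TRUE),
                       c("0", "1", "2", "3"))
  expect_equal(mamae(p2), 1.5)
  expect_equal(mamae(p2, printed_form = TRUE), sum(0:3) / 8)
})

test_that("confusion matrices conserve row sums", {
  p <- make_pred(sample(1:3, 40, replace = TRUE), K = 3, seed = 9)
  cm <- confusion(p)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(
    factor(p$y_true, levels = 1:3)))))
  perfect <- prediction_set(1:3, diag(3), c("a", "b", "c"))
  expect_equal(unname(confusion(perfect)), diag(3), ignore_attr = TRUE)
  one_col <- prediction_set(c(1, 2, 2), cbind(rep(1, 3), rep(0, 3)),
                            c("a", "b"), proba = FALSE)
  expect_true(all(confusion(one_col)[, 2] == 0))
})

test_that("reliability analysis scores calibration as expected", {
  # on-diagonal mass: zero miscalibration
  expect_equal(smece(list(f = rep(1, 200), y = rep(1, 200))), 0,
               tolerance = 1e-6)
  # maximal miscalibration approaches the upper bound
  expect_gt(smece(list(f = rep(1, 200), y = rep(0, 200))), 0.8)
  rc <- reliability(list(f = runif(500), y = rbinom(500, 1, 0.5)))
  expect_true(all(rc$smoothed >= 0 & rc$smoothed <= 1))
  expect_gt(rc$bandwidth, 0)
  expect_error(reliability(make_pred(rep(1:3, 5), K = 3)), "binary")
})

test_that("all bounded metrics stay in range on fuzzed prediction sets", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(4:25, 1)
    K <- sample(2:4, 1)
    y <- c(seq_len(K), sample(seq_len(K), n - K, replace = TRUE))
    p <- make_pred(y, K = K, seed = i)
    expect_true(balanced_accuracy(p) >= 0 && balanced_accuracy(p) <= 1)
    expect_true(accuracy(p) >= 0 && accuracy(p) <= 1)
    m <- mean_ap(p)
    expect_true(m >= 0 && m <= 1)
    f <- f1_macro(p)
    expect_true(f >= 0 && f <= 1)
    a <- auroc(p)
    expect_true(a >= 0 && a <= 1)
    expect_gte(mamae(p), 0)
  }
})

test_that("mAP of random scores approaches the mean class prevalence", {
  set.seed(11)
  n <- 4000
  y <- sample(1:3, n, replace = TRUE, prob = c(.6, .3, .1))
  reps <- vapply(1:20, function(i) mean_ap(make_pred(y, K = 3, seed = i)), 0)
  prevalence <- as.vector(table(y)) / n
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - mean(prevalence)), 3 * se + 0.01)
})

test_that("a metric report carries every headline quantity", {
  p <- make_pred(c(rep(1, 10), rep(2, 10)), K = 2, seed = 3)
  rep1 <- metric_report(p)
  expect_named(rep1, c("accuracy", "balanced_accuracy", "ap_per_class",
                       "map", "f1_macro", "auroc", "confusion", "smece"),
               ignore.order = TRUE)
  path <- tempfile(fileext = ".json")
  write_metric_report(rep1, path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path)
  expect_equal(back$balanced_accuracy, rep1$balanced_accuracy,
               tolerance = 1e-9)
  unlink(path)
})
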