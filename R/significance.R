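# Violation ratio of (almost) stochastic dominance of A over B on a uniform
# quantile grid: the share of the squared quantile-function gap where A's
# quantiles fall below B's. 0 = full dominance of A, 1 = full dominance of B;
# the two directions sum to 1. Degenerate (identical) samples return 0.5.
violation_ratio <- function(a, b, n_grid = 1000) {
  q <- (seq_len(n_grid) - 0.5) / n_grid
  qa <- stats::quantile(a, q, type = 1, names = FALSE)
  qb <- stats::quantile(b, q, type = 1, names = FALSE)
  gap <- qb - qa
  w2 <- sum(gap^2)
  if (w2 < 1e-24) return(0.5)
  sum(pmax(gap, 0)^2) / w2
}

#' Almost stochastic order comparison of two score samples
#'
#' Tests whether model A's score distribution is (almost) stochastically
#' dominant over model B's. The dominance-violation ratio `eps_min` is
#' computed from the empirical quantile functions on a uniform grid; a
#' bootstrap (resampling both sides with replacement, preserving group
#' sizes) provides a `(1 - alpha)` upper confidence bound. A is declared
#' dominant when the bound falls below `threshold` (0.2 by convention).
#'
#' @param a,b Numeric score vectors (>= 2 values each), e.g. balanced
#'   accuracies of repeated training runs; `a` is the candidate dominant
#'   model.
#' @param alpha Significance level; 0.05 by default.
#' @param n_bootstrap Bootstrap iterations; 1000 by default.
#' @param threshold Dominance threshold on the bound; 0.2 by default.
#' @param n_grid Quantile grid size for the violation integral.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `aso_result`: list with `eps_min` (point
#'   estimate), `upper_bound`, `alpha`, `n_bootstrap`, `dominant`,
#'   `degenerate`.
#' @export
aso <- function(a, b, alpha = 0.05, n_bootstrap = 1000, threshold = 0.2,
                n_grid = 1000, seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(a)),
            all(is.finite(b)))
  eps_obs <- violation_ratio(a, b, n_grid)
  degenerate <- stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12
  boots <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      violation_ratio(sample(a, length(a), replace = TRUE),
                      sample(b, length(b), replace = TRUE), n_grid)
    }, 0)
  })
  bound <- eps_obs + stats::sd(boots) * stats::qnorm(1 - alpha)
  bound <- min(max(bound, 0), 1)
  if (degenerate) bound <- max(bound, 0.5)
  structure(list(eps_min = eps_obs, upper_bound = bound, alpha = alpha,
                 n_bootstrap = n_bootstrap, threshold = threshold,
                 dominant = bound < threshold, degenerate = degenerate),
            class = "aso_result")
}

#' @export
print.aso_result <- function(x, ...) {
  cat(sprintf("ASO: eps_min = %.4g, %.0f%% upper bound = %.4g -> %s\n",
              x$eps_min, 100 * (1 - x$alpha), x$upper_bound,
              if (x$dominant) "A dominant" else "no dominance"))
  invisible(x)
}

#' Bootstrap power analysis for a score comparison
#'
#' Resamples both score sets with replacement (preserving group sizes) and
#' reports the fraction of resamples in which a one-sided Welch t-test of
#' "mean(A) > mean(B)" is significant at `alpha` -- an estimate of the
#' probability that a repeat of the experiment would detect the observed
#' direction of the difference.
#'
#' @param a,b Numeric score vectors.
#' @param n_iterations Bootstrap iterations; 5000 by default.
#' @param alpha Significance level of the inner test.
#' @param seed Integer seed.
#' @return Power estimate in `[0, 1]`.
#' @export
bootstrap_power <- function(a, b, n_iterations = 5000, alpha = 0.05,
                            seed = 1L) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_iterations)) {
      ra <- sample(a, length(a), replace = TRUE)
      rb <- sample(b, length(b), replace = TRUE)
      va <- stats::var(ra)
      vb <- stats::var(rb)
      if (va + vb < 1e-24) {
        sig <- mean(ra) > mean(rb)
      } else {
        se <- sqrt(va / length(ra) + vb / length(rb))
        tval <- (mean(ra) - mean(rb)) / se
        df <- se^4 / (va^2 / (length(ra)^2 * (length(ra) - 1)) +
                        vb^2 / (length(rb)^2 * (length(rb) - 1)))
        sig <- stats::pt(tval, df, lower.tail = FALSE) < alpha
      }
      if (isTRUE(sig)) hits <- hits + 1L
    }
    hits / n_iterations
  })
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Pairwise model comparison report
#'
#' Runs [aso()] in both directions and [bootstrap_power()] for every ordered
#' model pair of a named list of score vectors, at a Bonferroni-corrected
#' level.
#'
#' @param scores Named list of numeric score vectors (one per model).
#' @param metric Metric name carried into the report.
#' @param alpha Family-wise significance level.
#' @param m_comparisons Total comparisons for the Bonferroni correction;
#'   defaults to the number of ordered pairs.
#' @param seed Integer seed.
#' @return Data frame with one row per ordered pair: eps_min, upper bound,
#'   power, corrected alpha and verdict.
#' @export
compare_models <- function(scores, metric = "score", alpha = 0.05,
                           m_comparisons = NULL, seed = 1L) {
  stopifnot(is.list(scores), length(scores) >= 2, !is.null(names(scores)))
  pairs <- expand.grid(a = names(scores), b = names(scores),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  m <- m_comparisons %||% nrow(pairs)
  corrected <- bonferroni(alpha, m)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    an <- pairs$a[i]; bn <- pairs$b[i]
    res <- aso(scores[[an]], scores[[bn]], alpha = corrected,
               seed = child_seed(seed, i))
    pw <- bootstrap_power(scores[[an]], scores[[bn]], n_iterations = 1000,
                          alpha = corrected, seed = child_seed(seed, i + 1000L))
    data.frame(model_a = an, model_b = bn, metric = metric,
               eps_min = res$eps_min, upper_bound = res$upper_bound,
               power = pw, corrected_alpha = corrected,
               dominant = res$dominant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
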