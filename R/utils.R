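#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are unaffected.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a base seed and an index.
# Keeps results within 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# Truncated-normal draws via inverse-CDF; lower truncation only.
rtruncnorm_min <- function(n, mean, sd, min) {
  if (sd <= 0) return(rep(max(mean, min), n))
  p_lo <- stats::pnorm(min, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Per-row z-normalization of a channels x time matrix; constant rows map to 0.
znorm_rows <- function(x) {
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  sdev[sdev < 1e-12] <- 1
  (x - mu) / sdev
}

`%||%` <- function(a, b) if (is.null(a)) b else a
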