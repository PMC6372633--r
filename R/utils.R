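# Internal helpers shared across modules: seed plumbing, split-R-hat,
# a univariate slice sampler, and small numerical utilities.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `code`, and restores the caller's RNG
#' state, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# Named substream of a base seed. Every stochastic operation draws from its
# own substream so stages can be rerun independently without changing the
# draws of other stages. Result is kept inside 32-bit integer range.
substream <- function(seed, name) {
  ch <- utf8ToInt(name)
  h <- sum(ch * seq_along(ch)) %% 100000L
  as.integer((as.numeric(seed) %% 1000003L) * 2011L + h * 7919L) %% 214748329L
}

# Split R-hat (potential scale reduction) for one scalar parameter.
# `draws` is an iterations x chains matrix of post-warmup draws.
split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- n %/% 2L
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Univariate slice sampler (stepping out + shrinkage; Neal 2003).
# `logf` is the unnormalised log density; returns one new draw.
slice_sample1 <- function(x0, logf0, w = 1, max_step = 30L) {
  logf <- function(x) { v <- logf0(x); if (is.finite(v)) v else -Inf }
  y <- logf(x0) - stats::rexp(1L)
  if (!is.finite(y)) return(x0)
  u <- stats::runif(1L)
  l <- x0 - w * u
  r <- l + w
  k <- max_step
  while (k > 0L && logf(l) > y) { l <- l - w; k <- k - 1L }
  k <- max_step
  while (k > 0L && logf(r) > y) { r <- r + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1L, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# Type-7 quantile of the columns of a sorted matrix, vectorised over columns
# with per-column counts `n` (values beyond n in a column are ignored).
# Returns a vector of quantiles, NA where n < 1.
colwise_type7 <- function(sorted, n, p) {
  h <- 1 + (n - 1) * p
  lo <- floor(h)
  hi <- ceiling(h)
  ncolm <- ncol(sorted)
  out <- rep(NA_real_, ncolm)
  ok <- n >= 1L
  idx_lo <- cbind(pmax(lo[ok], 1L), which(ok))
  idx_hi <- cbind(pmax(hi[ok], 1L), which(ok))
  vlo <- sorted[idx_lo]
  vhi <- sorted[idx_hi]
  out[ok] <- vlo + (h[ok] - lo[ok]) * (vhi - vlo)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
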