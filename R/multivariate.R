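# Distance-based multivariate analysis: Euclidean distances (optionally on
# genotype-averaged profiles), full-factorial PERMANOVA with sequential
# (Type-I) sums of squares from the Gower-centred inner-product matrix, and
# PCA with iterative low-rank missing-value imputation.

#' Euclidean distances between samples or genotype-averaged profiles
#'
#' @param x a [feature_table()] or numeric matrix (samples x features).
#' @param average_by_genotype average replicate profiles to one profile per
#'   genotype before computing distances (requires a feature table).
#' @param pairwise use pairwise-complete features for each sample pair,
#'   rescaled to the full feature count; without it missing values are an
#'   error (impute first).
#' @return a `dist` object with labels.
#' @export
euclidean_distances <- function(x, average_by_genotype = FALSE,
                                pairwise = FALSE) {
  if (inherits(x, "feature_table")) {
    m <- x$abundance
    if (average_by_genotype) {
      g <- factor(x$meta$genotype)
      m <- do.call(rbind, lapply(levels(g), function(lv)
        colMeans(m[g == lv, , drop = FALSE], na.rm = TRUE)))
      rownames(m) <- levels(g)
    }
  } else {
    m <- as.matrix(x)
    if (average_by_genotype)
      stop("average_by_genotype requires a feature_table with metadata")
  }
  if (any(colSums(!is.na(m)) == 0L))
    stop("schema error: feature(s) with no observed values")
  if (anyNA(m)) {
    if (!pairwise)
      stop("missing values present; impute first or set pairwise = TRUE")
    p <- ncol(m)
    pres <- !is.na(m)
    m0 <- m; m0[!pres] <- 0
    # pairwise-complete squared distance, rescaled by p / n_complete
    cross <- tcrossprod(m0)
    n_complete <- tcrossprod(pres * 1)
    ssum_both <- tcrossprod(m0^2, pres) # sum of x_i^2 over features seen in both
    d2 <- ssum_both + t(ssum_both) - 2 * cross
    if (any(n_complete == 0))
      stop("schema error: sample pair with no shared observed features")
    d2 <- d2 * p / n_complete
    d2[d2 < 0] <- 0
    return(stats::as.dist(structure(sqrt(d2),
                                    dimnames = list(rownames(m), rownames(m)))))
  }
  stats::dist(m)
}

#' Full-factorial PERMANOVA with permutation p-values
#'
#' Partitions the Gower-centred inner-product matrix of a distance matrix by
#' the model terms in formula order (sequential, Type-I sums of squares), and
#' tests each term's pseudo-F against free row permutations with the add-one
#' convention `p = (1 + #permuted F >= F_obs) / (1 + n_perm)`.
#'
#' @param d a `dist` or symmetric distance matrix over samples.
#' @param meta data.frame of sample factors, rows aligned with `d`.
#' @param formula right-hand-side model formula over columns of `meta`,
#'   e.g. `~ genotype * tissue * regime`.
#' @param n_perm number of permutations (study default 10000).
#' @param seed integer seed.
#' @return a `permanova` data.frame (`term, df, ss, ms, pseudo_f, p`) with
#'   residual and total rows; attributes carry `n_perm`, `seed` and a
#'   `degenerate` flag when total SS is zero (tests undefined).
#' @export
permanova <- function(d, meta, formula = ~ genotype * tissue * regime,
                      n_perm = 10000L, seed = 1L) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(nrow(meta) == n)
  A <- -0.5 * dm^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A) # Gower centring

  labels <- attr(stats::terms(formula), "term.labels")
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_prev <- matrix(1 / n, n, n)
  rank_prev <- 1L
  projectors <- list(); dfs <- integer(); kept <- character()
  for (j in seq_along(labels)) {
    X <- stats::model.matrix(stats::reformulate(labels[seq_len(j)]), meta)
    Hj <- hat(X)
    rank_j <- qr(X)$rank
    df_j <- rank_j - rank_prev
    if (df_j <= 0L) {
      warning("term '", labels[j], "' has 0 df and was dropped")
      next
    }
    projectors[[length(projectors) + 1L]] <- Hj - H_prev
    dfs <- c(dfs, df_j)
    kept <- c(kept, labels[j])
    H_prev <- Hj
    rank_prev <- rank_j
  }
  P_res <- diag(n) - H_prev
  df_res <- n - rank_prev

  ss_total <- sum(diag(G))
  degenerate <- ss_total <= 1e-12 * n
  ss <- vapply(projectors, function(P) sum(P * G), 0)
  ss_res <- sum(P_res * G)
  ms <- ss / dfs
  ms_res <- ss_res / df_res
  f_obs <- ms / ms_res

  pvals <- rep(NA_real_, length(kept))
  if (!degenerate && n_perm > 0L) {
    counts <- integer(length(kept))
    # permutations that reproduce the observed grouping recompute F through a
    # different summation order; count ties up to floating-point noise so the
    # permutation p matches exhaustive enumeration
    eps <- 1e-8 * pmax(abs(f_obs), 1)
    local_seed(substream(seed, "permanova"), {
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- G[p, p]
        ssp <- vapply(projectors, function(P) sum(P * Gp), 0)
        fp <- (ssp / dfs) / (sum(P_res * Gp) / df_res)
        counts <- counts + (fp >= f_obs - eps)
      }
    })
    pvals <- (1 + counts) / (1 + n_perm)
  }
  if (degenerate) {
    f_obs <- rep(NA_real_, length(kept))
    warning("total sum of squares is zero; pseudo-F undefined (degenerate)")
  }

  out <- data.frame(term = c(kept, "Residual", "Total"),
                    df = c(dfs, df_res, n - 1L),
                    ss = c(ss, ss_res, ss_total),
                    ms = c(ms, ms_res, NA_real_),
                    pseudo_f = c(f_obs, NA_real_, NA_real_),
                    p = c(pvals, NA_real_, NA_real_))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "degenerate") <- degenerate
  class(out) <- c("permanova", "data.frame")
  out
}

#' Iterative low-rank imputation of missing values
#'
#' Initializes missing cells at feature means, then alternates a
#' rank-`n_components` truncated SVD reconstruction of the column-centred
#' matrix with refilling of the missing cells, until the RMS change of the
#' imputed cells drops below `tol` or `max_iter` is reached. Observed cells
#' are never altered.
#'
#' @param x numeric matrix with missing values (or a [feature_table()], in
#'   which case `completed` is returned as a feature table with the same
#'   metadata); every feature needs at least one observed value.
#' @param n_components reconstruction rank (default 5).
#' @param max_iter iteration cap (default 200).
#' @param tol convergence tolerance on imputed cells (default 1e-6, relative
#'   to the RMS of the data).
#' @return list with `completed` (matrix or feature table), `converged`,
#'   `iterations`.
#' @export
impute_pca <- function(x, n_components = 5L, max_iter = 200L, tol = 1e-6) {
  if (inherits(x, "feature_table")) {
    out <- impute_pca(x$abundance, n_components, max_iter, tol)
    x$abundance <- out$completed
    x <- ft_append_log(x, list(step = "impute_pca",
                               n_components = n_components,
                               iterations = out$iterations,
                               converged = out$converged))
    out$completed <- x
    return(out)
  }
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(list(completed = x, converged = TRUE, iterations = 0L))
  if (any(colSums(!miss) == 0L))
    stop("feature(s) with no observed values cannot be imputed")
  mu <- colMeans(x, na.rm = TRUE)
  xf <- x
  xf[miss] <- matrix(mu, nrow(x), ncol(x), byrow = TRUE)[miss]
  scale_ref <- sqrt(mean(xf^2))
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ctr <- colMeans(xf)
    sv <- svd(sweep(xf, 2, ctr), nu = k, nv = k)
    recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
    recon <- sweep(recon, 2, ctr, "+")
    new_vals <- recon[miss]
    delta <- sqrt(mean((new_vals - xf[miss])^2))
    xf[miss] <- new_vals
    if (delta < tol * max(scale_ref, 1e-12)) { converged <- TRUE; break }
  }
  list(completed = xf, converged = converged, iterations = it)
}

#' Principal component analysis by singular value decomposition
#'
#' Column-centred (and unit-variance scaled when `scale = TRUE`) SVD of a
#' complete matrix. Zero-variance columns are dropped with a warning when
#' scaling.
#'
#' @param x complete numeric matrix (samples x features).
#' @param scale scale columns to unit variance (study default TRUE).
#' @return list with `scores`, `loadings`, `sdev` and `var_frac` (fractions
#'   sum to 1).
#' @export
pca <- function(x, scale = TRUE) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values present; impute first")
  ctr <- sweep(x, 2, colMeans(x))
  if (scale) {
    s <- apply(x, 2, stats::sd)
    zero <- s == 0 | is.na(s)
    if (any(zero)) {
      warning(sum(zero), " zero-variance column(s) dropped before scaling")
      ctr <- ctr[, !zero, drop = FALSE]
      s <- s[!zero]
    }
    ctr <- sweep(ctr, 2, s, "/")
  }
  sv <- svd(ctr)
  keep <- sv$d > sv$d[1] * 1e-12
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  rownames(scores) <- rownames(x)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(ctr)
  var_frac <- sv$d[keep]^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings,
       sdev = sv$d[keep] / sqrt(max(1, nrow(x) - 1)), var_frac = var_frac)
}
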