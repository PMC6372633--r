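# Baker's gamma index: for every pair of leaves, record in each tree the
# number of clusters present at the moment the pair first co-clusters (n - s
# after merge step s; large values mean the pair merges early / sits deep).
# Gamma is the Goodman-Kruskal rank correlation between the two pair-depth
# vectors, with tied pairs ignored — Baker's original definition, which is
# what makes the index attain exactly -1 on fully reversed 4-leaf trees and
# +1 on identical trees. Significance comes from permuting the leaf labels
# of one tree.

# Pair co-clustering depth matrix: M[i, j] = n - s where s is the merge step
# at which leaves i and j first share a cluster.
pair_depth_matrix <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  M <- matrix(NA_real_, n, n, dimnames = list(tree$labels, tree$labels))
  for (s in seq_len(n - 1L)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    M[ma, mb] <- n - s
    M[mb, ma] <- n - s
    members[[s]] <- c(ma, mb)
  }
  M
}

# Goodman-Kruskal gamma between two integer vectors, computed from the joint
# contingency table in O(r * c) after tabulation.
gk_gamma <- function(u, v) {
  lu <- sort(unique(u)); lv <- sort(unique(v))
  r <- length(lu); cc <- length(lv)
  iu <- match(u, lu); iv <- match(v, lv)
  T <- matrix(tabulate((iv - 1L) * r + iu, r * cc), r, cc)
  # row_suff[i, j] = sum_{k >= i} T[k, j]
  row_suff <- matrix(0, r, cc)
  row_suff[r, ] <- T[r, ]
  if (r > 1L) for (i in (r - 1L):1L) row_suff[i, ] <- row_suff[i + 1L, ] + T[i, ]
  # both_suff[i, j] = sum_{k >= i, l >= j};  both_pref_col[i, j] = sum_{k >= i, l <= j}
  both_suff <- t(apply(row_suff, 1, function(v) rev(cumsum(rev(v)))))
  both_pref <- t(apply(row_suff, 1, cumsum))
  if (cc == 1L) { both_suff <- row_suff; both_pref <- row_suff }
  gt <- matrix(0, r, cc) # strictly-greater-in-both counts per cell
  if (r > 1L && cc > 1L)
    gt[seq_len(r - 1L), seq_len(cc - 1L)] <- both_suff[-1L, -1L, drop = FALSE]
  lt <- matrix(0, r, cc) # greater row, strictly smaller column
  if (r > 1L && cc > 1L)
    lt[seq_len(r - 1L), 2L:cc] <- both_pref[-1L, seq_len(cc - 1L), drop = FALSE]
  conc <- sum(T * gt)
  disc <- sum(T * lt)
  if (conc + disc == 0) return(NA_real_)
  (conc - disc) / (conc + disc)
}

#' Baker's gamma index between two dendrograms
#'
#' @param tree1,tree2 `hclust` objects over the same leaf-label set.
#' @return gamma in `[-1, 1]`; 1 for identical trees.
#' @export
bakers_gamma <- function(tree1, tree2) {
  if (!setequal(tree1$labels, tree2$labels) ||
      length(tree1$labels) != length(tree2$labels))
    stop("trees must share an identical leaf-label set")
  M1 <- pair_depth_matrix(tree1)
  M2 <- pair_depth_matrix(tree2)[tree1$labels, tree1$labels]
  ut <- upper.tri(M1)
  gk_gamma(M1[ut], M2[ut])
}

#' Label-permutation test for Baker's gamma
#'
#' Permutes the leaf labels of the second tree `n_perm` times (study default
#' 1000) and reports `p = (1 + #permuted gamma >= observed) / (1 + n_perm)`.
#'
#' @param tree1,tree2 `hclust` objects over the same leaf-label set.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with `gamma`, `p`, `n_perm`, `seed`, and the permuted null
#'   values `null`.
#' @export
gamma_permutation_test <- function(tree1, tree2, n_perm = 1000L, seed = 1L) {
  if (!setequal(tree1$labels, tree2$labels))
    stop("trees must share an identical leaf-label set")
  M1 <- pair_depth_matrix(tree1)
  M2 <- pair_depth_matrix(tree2)[tree1$labels, tree1$labels]
  ut <- upper.tri(M1)
  u1 <- M1[ut]
  obs <- gk_gamma(u1, M2[ut])
  n <- nrow(M1)
  null <- local_seed(substream(seed, "bakers_gamma"), {
    vapply(seq_len(n_perm), function(b) {
      p <- sample.int(n)
      gk_gamma(u1, M2[p, p][ut])
    }, 0)
  })
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + n_perm)
  list(gamma = obs, p = p, n_perm = n_perm, seed = seed, null = null)
}
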