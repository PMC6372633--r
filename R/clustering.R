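# Agglomerative clustering with the Ward variant in which the dissimilarities
# are squared before cluster updating: the Lance-Williams Ward recurrence is
# applied to the squared input distances. On squared Euclidean input each
# merge height equals twice the increase in the within-cluster sum of squares
# (the Ward objective), which is what the brute-force oracle in the test
# suite recomputes.

#' Hierarchical clustering, Ward on squared dissimilarities
#'
#' @param d a `dist` object or symmetric distance matrix (the raw, unsquared
#'   dissimilarities; they are squared internally before updating).
#' @return an object of class `hclust` (merge, height, order, labels); heights
#'   are non-decreasing. Ties are broken deterministically in favour of the
#'   lowest index pair.
#' @export
hcluster_ward_squared <- function(d) {
  D <- as.matrix(d)^2
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 observations to cluster")
  labels <- rownames(D) %||% as.character(seq_len(n))
  diag(D) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n) # hclust convention: negative = singleton leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    mv <- min(D[active, active])
    cand <- which(D == mv, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2] & active[cand[, 1]] & active[cand[, 2]], ,
                 drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    height[s] <- mv
    a <- id[i]; b <- id[j]
    # order the pair as hclust does: singletons before clusters; two
    # singletons by increasing leaf index, two clusters by merge step
    merge[s, ] <- if (a < 0 && b < 0) c(max(a, b), min(a, b))
                  else if (a < 0) c(a, b) else if (b < 0) c(b, a)
                  else c(min(a, b), max(a, b))
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks)) {
      tot <- size[i] + size[j] + size[ks]
      D[i, ks] <- D[ks, i] <-
        ((size[i] + size[ks]) * D[i, ks] + (size[j] + size[ks]) * D[j, ks] -
           size[ks] * D[i, j]) / tot
    }
    size[i] <- size[i] + size[j]
    id[i] <- s
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }

  # leaf order by iterative expansion of the final merge
  ord <- integer(0)
  stack <- list(n - 1L)
  expand <- function(node) {
    out <- integer(0)
    st <- list(node)
    while (length(st)) {
      nd <- st[[length(st)]]
      st[[length(st)]] <- NULL
      if (nd < 0) out <- c(out, -nd)
      else st <- c(st, list(merge[nd, 2L]), list(merge[nd, 1L]))
    }
    out
  }
  ord <- expand(n - 1L)

  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "ward_squared",
                 dist.method = "euclidean"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Applies the first `n - k` merges, so ties at the cut height are resolved
#' by merge order. Cuts are nested: the cut at `k - 1` merges exactly two
#' clusters of the `k` cut.
#'
#' @param tree an `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels in `1..k`, named by leaf label,
#'   numbered by first leaf appearance.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  grp <- seq_len(n)
  reps <- integer(max(0L, n - 1L))
  n_merge <- n - k
  for (s in seq_len(n_merge)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ra <- if (a < 0) -a else reps[a]
    rb <- if (b < 0) -b else reps[b]
    grp[grp == grp[rb]] <- grp[ra]
    reps[s] <- ra
  }
  out <- as.integer(factor(grp, levels = unique(grp)))
  names(out) <- tree$labels
  out
}

#' Serialize a dendrogram to Newick
#'
#' @param tree an `hclust` object.
#' @param path file path.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
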