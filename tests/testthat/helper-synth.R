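# Shared fixtures: small synthetic studies and hand-built objects used across
# test files. Everything is generated in code; no data files.

small_spec <- function(seed = 1L, n_genotypes = 4L, n_replicates = 5L,
                       n_features = 80L) {
  design_spec(n_genotypes = n_genotypes, n_replicates = n_replicates,
              n_features = n_features, seed = seed)
}

small_study <- function(seed = 1L, ...) synth_study(small_spec(seed = seed), ...)

# feature table built by hand, complete factorial over g genotypes x 2
# regimes x 2 tissues with r replicates; values from `fill` (recycled) or a
# function(n) generating them
manual_table <- function(g = 2L, r = 3L, n_feat = 4L, fill = NULL,
                         gen = stats::rnorm) {
  meta <- expand.grid(replicate = seq_len(r), regime = c("control", "drought"),
                      tissue = c("aboveground", "belowground"),
                      genotype = sprintf("G%02d", seq_len(g)),
                      stringsAsFactors = FALSE)
  meta$plant_id <- with(meta, sprintf("%s_%s_r%d", genotype,
                                      substr(regime, 1, 1), replicate))
  meta$sample_id <- paste(meta$plant_id, substr(meta$tissue, 1, 2), sep = "_")
  n <- nrow(meta)
  vals <- if (!is.null(fill)) rep_len(fill, n * n_feat) else abs(gen(n * n_feat)) + 1
  m <- matrix(vals, n, n_feat,
              dimnames = list(NULL, sprintf("F%03d", seq_len(n_feat))))
  feature_table(m, meta)
}

# 4-leaf dendrograms with an explicit merge order (leaves labelled L1..L4)
tree4 <- function(first, second) {
  structure(list(merge = rbind(c(-first[1], -first[2]),
                               c(-second[1], -second[2]),
                               c(1L, 2L)),
                 height = c(1, 2, 3), order = 1:4,
                 labels = paste0("L", 1:4), method = "ward_squared"),
            class = "hclust")
}

# random dendrogram over n leaves from random coordinates
random_tree <- function(n, seed, labels = paste0("L", seq_len(n))) {
  pts <- local_seed_test(seed, matrix(stats::rnorm(n * 3), n, 3))
  rownames(pts) <- labels
  hcluster_ward_squared(stats::dist(pts))
}

local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# brute-force Ward oracle on coordinates: at every step recompute the Ward
# objective increase for all cluster pairs and merge the minimizer. Returns
# the sequence of merged leaf-sets and the objective increases.
ward_oracle <- function(pts) {
  n <- nrow(pts)
  clusters <- lapply(seq_len(n), identity)
  steps <- list()
  deltas <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      A <- clusters[[i]]; B <- clusters[[j]]
      cA <- colMeans(pts[A, , drop = FALSE]); cB <- colMeans(pts[B, , drop = FALSE])
      d <- length(A) * length(B) / (length(A) + length(B)) * sum((cA - cB)^2)
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    steps[[length(steps) + 1L]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    deltas <- c(deltas, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(steps = steps, deltas = deltas)
}

# leaf-sets merged at each step of an hclust tree
merge_leaf_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  members <- vector("list", n - 1L)
  out <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    members[[s]] <- c(ma, mb)
    out[[s]] <- sort(members[[s]])
  }
  out
}
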