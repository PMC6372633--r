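# Distances, PERMANOVA (incl. the vegan cross-check), imputation and PCA.

test_that("euclidean distances: identity, 3-4-5, averaging idempotence", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- as.matrix(euclidean_distances(m))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 5)

  # averaging identical replicates equals any single replicate
  ft <- manual_table(g = 2, r = 5, n_feat = 3, fill = 1)
  ft$abundance[ft$meta$genotype == "G02", ] <- 2
  davg <- as.matrix(euclidean_distances(ft, average_by_genotype = TRUE))
  i2 <- which(ft$meta$genotype == "G02")[1]
  single <- rbind(ft$abundance[1, ], ft$abundance[i2, ])
  expect_equal(unname(davg), unname(as.matrix(stats::dist(single))))

  ft$abundance[, 2] <- NA
  expect_error(euclidean_distances(ft), "no observed values")
  ft2 <- manual_table(g = 1, r = 3, n_feat = 3, fill = 2)
  ft2$abundance[1, 1] <- NA
  expect_error(euclidean_distances(ft2), "impute first")
  expect_s3_class(euclidean_distances(ft2, pairwise = TRUE), "dist")
})

test_that("permanova partitions SS exactly and matches vegan::adonis2", {
  set.seed(101)
  n <- 24
  meta <- expand.grid(genotype = c("g1", "g2", "g3"),
                      tissue = c("ab", "be"), regime = c("c", "d"),
                      rep = 1:2)[, 1:3]
  x <- matrix(rnorm(n * 6), n, 6)
  x[meta$tissue == "ab", 1] <- x[meta$tissue == "ab", 1] + 2
  d <- stats::dist(x)
  pm <- permanova(d, meta, ~ genotype * tissue * regime, n_perm = 99, seed = 1)

  # additivity: term SS + residual SS = total SS
  ss <- pm$ss
  expect_equal(sum(ss[seq_len(nrow(pm) - 1)]), ss[nrow(pm)], tolerance = 1e-8)
  expect_true(all(ss > -1e-8))
  expect_equal(pm$df[nrow(pm)], n - 1)

  ad <- vegan::adonis2(d ~ genotype * tissue * regime, data = meta,
                       permutations = 99, by = "terms")
  expect_equal(pm$ss[seq_len(7)], ad$SumOfSqs[seq_len(7)], tolerance = 1e-8)
  expect_equal(pm$pseudo_f[seq_len(7)], ad$F[seq_len(7)], tolerance = 1e-8)
})

test_that("permanova p-values are invariant to factor level relabelling", {
  set.seed(103)
  meta <- data.frame(grp = rep(c("a", "b", "c"), each = 4))
  x <- matrix(rnorm(36), 12, 3)
  d <- stats::dist(x)
  p1 <- permanova(d, meta, ~ grp, n_perm = 199, seed = 7)$p[1]
  meta2 <- data.frame(grp = c(a = "z", b = "q", c = "m")[meta$grp])
  p2 <- permanova(d, meta2, ~ grp, n_perm = 199, seed = 7)$p[1]
  expect_identical(p1, p2)
})

test_that("degenerate all-identical data is flagged, not tested", {
  meta <- data.frame(grp = rep(c("a", "b"), each = 2))
  d <- stats::dist(matrix(1, 4, 3))
  expect_warning(pm <- permanova(d, meta, ~ grp, n_perm = 19, seed = 1),
                 "degenerate")
  expect_true(attr(pm, "degenerate"))
  expect_true(all(is.na(pm$pseudo_f[1])))
})

test_that("impute_pca: identity, constant column, low-rank recovery", {
  x <- matrix(rnorm(50), 10, 5)
  r <- impute_pca(x)
  expect_identical(r$completed, x)
  expect_equal(r$iterations, 0L)

  xc <- cbind(x, 7)
  xc[3, 6] <- NA
  rc <- impute_pca(xc, n_components = 2)
  expect_equal(rc$completed[3, 6], 7, tolerance = 1e-8)

  set.seed(11)
  M <- outer(rnorm(30), rnorm(20))
  idx <- sample(length(M), 60)
  Mna <- M; Mna[idx] <- NA
  rr <- impute_pca(Mna, n_components = 1, tol = 1e-9)
  expect_true(rr$converged)
  rel <- abs(rr$completed[idx] - M[idx]) / pmax(abs(M[idx]), 1e-6)
  expect_lt(stats::median(rel), 0.01)
  # observed cells never altered
  expect_identical(rr$completed[-idx], M[-idx])
})

test_that("pca: variance fractions, SVD identities, zero-variance columns", {
  two <- rbind(c(0, 0, 0), c(1, 2, 2))
  p2 <- pca(two, scale = FALSE)
  expect_equal(p2$var_frac[1], 1)

  set.seed(12)
  x <- matrix(rnorm(80), 16, 5)
  p <- pca(x, scale = TRUE)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-10)
  # scores Gram matrix reproduces the centred/scaled data inner products
  xs <- scale(x)
  attr(xs, "scaled:center") <- attr(xs, "scaled:scale") <- NULL
  expect_equal(tcrossprod(p$scores), tcrossprod(xs), tolerance = 1e-8,
               ignore_attr = TRUE)

  xz <- cbind(x, 5)
  expect_warning(pz <- pca(xz, scale = TRUE), "zero-variance")
  expect_equal(ncol(pz$loadings), ncol(p$loadings))
})
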