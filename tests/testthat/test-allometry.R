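# Hierarchical allometry: exact recovery in degenerate settings, shrinkage,
# pooling, RMF arithmetic and the heteroscedastic drought tests.

test_that("noiseless single-accession identity data recovers k = 1, ln b = 0", {
  b <- data.frame(plant_id = paste0("p", 1:6), genotype = "G1",
                  regime = "control",
                  shoot_dw_g = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  b$root_dw_g <- b$shoot_dw_g
  fit <- fit_allometry_bhm(b, chains = 2, iter = 400, warmup = 400, seed = 2)
  expect_lt(abs(fit$summary$k_mean - 1), 0.02)
  expect_lt(abs(fit$summary$lnb_mean - 0), 0.02)
  expect_true(all(fit$summary$k_lo <= fit$summary$k_mean &
                    fit$summary$k_mean <= fit$summary$k_hi))
})

test_that("posterior concentrates on truth as noise vanishes", {
  spec <- small_spec(seed = 71, n_genotypes = 6)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  b <- simulate_biomass(design, truth, noise_sd = 1e-3, seed = 71)
  b <- b[b$regime == "control", ]
  fit <- fit_allometry_bhm(b, chains = 2, iter = 400, warmup = 400, seed = 3)
  expect_lt(max(abs(fit$summary$k_mean - truth$k)), 0.01)
  post_sd <- apply(fit$draws[, grep("^k\\[", colnames(fit$draws))], 2, sd)
  expect_lt(max(post_sd), 0.02)
})

test_that("a two-plant accession shrinks toward the population mean", {
  spec <- design_spec(n_genotypes = 8, n_replicates = 5, n_features = 60,
                      seed = 81)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  b <- simulate_biomass(design, truth, noise_sd = 0.15, seed = 81)
  b <- b[b$regime == "control", ]
  # keep two plants of the first accession and force their exact-fit OLS
  # slope to an implausible 3.0, far outside the population range
  g1 <- unique(b$genotype)[1]
  idx <- which(b$genotype == g1)
  b <- b[-idx[3:length(idx)], ]
  idx <- which(b$genotype == g1)
  x <- log(b$shoot_dw_g[idx])
  b$root_dw_g[idx] <- exp(-1.8 + 3.0 * (x - mean(x)) + 0.35 * mean(x))
  fit <- suppressWarnings(fit_allometry_bhm(b, chains = 2, iter = 500,
                                            warmup = 500, seed = 4))
  row <- fit$summary[fit$summary$genotype == g1, ]
  expect_equal(row$k_ols, 3, tolerance = 1e-6)
  mu <- fit$population["mu_k"]
  # partial pooling pulls the posterior far off the wild OLS slope
  expect_lt(abs(row$k_mean - mu), 0.5 * abs(row$k_ols - mu))
})

test_that("population mean k lies inside the hull of accession OLS slopes", {
  spec <- small_spec(seed = 91, n_genotypes = 10)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  b <- simulate_biomass(design, truth, noise_sd = 0.15, seed = 91)
  b <- b[b$regime == "control", ]
  fit <- suppressWarnings(fit_allometry_bhm(b, chains = 2, iter = 400,
                                            warmup = 400, seed = 5))
  ols <- fit$summary$k_ols
  expect_gte(fit$population["mu_k"], min(ols))
  expect_lte(fit$population["mu_k"], max(ols))
})

test_that("input validation rejects bad biomass tables", {
  b <- data.frame(plant_id = c("a", "b"), genotype = "G1", regime = "control",
                  shoot_dw_g = c(0.1, -0.2), root_dw_g = c(0.05, 0.1))
  expect_error(fit_allometry_bhm(b), "strictly positive")
  b2 <- data.frame(plant_id = "a", genotype = "G1", regime = "control",
                   shoot_dw_g = 0.1, root_dw_g = 0.05)
  expect_error(fit_allometry_bhm(b2), "at least 2 plants")
})

test_that("RMF is exact per-plant arithmetic averaged per accession", {
  b <- data.frame(plant_id = paste0("p", 1:4),
                  genotype = c("G1", "G1", "G2", "G2"), regime = "control",
                  shoot_dw_g = c(0.3, 0.3, 0.2, 0.1),
                  root_dw_g = c(0.1, 0.1, 0.2, 0.1))
  rmf <- compute_rmf(b)
  expect_equal(rmf$rmf[rmf$genotype == "G1"], 0.25)  # 0.1 / 0.4
  expect_equal(rmf$rmf[rmf$genotype == "G2"], 0.5)   # x = y
  st <- small_study(seed = 15)
  r2 <- compute_rmf(st$biomass)
  expect_true(all(r2$rmf > 0 & r2$rmf < 1))
  # agrees with a scalar recomputation for every row
  manual <- tapply(st$biomass$root_dw_g /
                     (st$biomass$shoot_dw_g + st$biomass$root_dw_g),
                   st$biomass$genotype, mean)
  expect_equal(r2$rmf, as.numeric(manual[r2$genotype]))
})

test_that("drought biomass tests: identity, known effect, percent change", {
  # identical regime samples -> difference 0, p = 1
  b <- data.frame(plant_id = paste0("p", 1:8), genotype = "G1",
                  regime = rep(c("control", "drought"), each = 4),
                  shoot_dw_g = rep(c(0.2, 0.25, 0.3, 0.35), 2),
                  root_dw_g = rep(c(0.1, 0.1, 0.12, 0.14), 2))
  res <- test_drought_biomass(b)
  expect_true(all(abs(res$estimate) < 1e-12))
  expect_true(all(res$p > 0.999))

  # percent change formula: cell means 0.10 -> 0.223 is +123%
  expect_equal(100 * (0.223 - 0.10) / 0.10, 123, tolerance = 1e-12)

  # planted +50% root multiplier with small noise is detected
  spec <- small_spec(seed = 25, n_genotypes = 4)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  truth$drought_root_mult[] <- 1; truth$drought_shoot_mult[] <- 1
  g1 <- names(truth$drought_root_mult)[1]
  truth$drought_root_mult[g1] <- 1.5
  bio <- simulate_biomass(design, truth, noise_sd = 0.05, seed = 25)
  res2 <- test_drought_biomass(bio)
  row <- res2[res2$genotype == g1 & res2$trait == "root", ]
  expect_lt(row$p, 0.05)
  expect_gt(row$estimate, 0)
  expect_gt(row$pct_change, 0)

  # a cell with < 2 plants is skipped and flagged
  b3 <- b[-(5:7), ]
  res3 <- test_drought_biomass(b3)
  expect_true(all(!res3$tested))
  expect_true(all(is.na(res3$p)))
})
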