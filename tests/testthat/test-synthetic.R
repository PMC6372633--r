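# Synthetic-data generator: design arithmetic, determinism, biomass
# allometry recovery, and the clean-table / planted-effect contracts.

test_that("design arithmetic and validation", {
  d <- generate_design(design_spec(n_genotypes = 30, n_replicates = 5))
  expect_equal(length(unique(d$plant_id)), 300)   # 30 x 2 x 5 plants
  expect_equal(nrow(d), 600)                       # two tissue samples each
  tab <- table(d$genotype, d$regime) / 2           # per-tissue replicate count
  expect_true(all(tab == 5))

  d2 <- generate_design(design_spec(n_genotypes = 2, n_replicates = 2,
                                    n_features = 60))
  expect_equal(length(unique(d2$plant_id)), 8)

  expect_error(design_spec(n_genotypes = 1), "configuration error")
  expect_error(design_spec(n_replicates = 1), "configuration error")
})

test_that("same seed gives bit-identical outputs, different seed differs", {
  a <- small_study(seed = 11)
  b <- small_study(seed = 11)
  expect_identical(a$design, b$design)
  expect_identical(a$table$abundance, b$table$abundance)
  expect_identical(a$biomass, b$biomass)
  expect_identical(a$blanks, b$blanks)
  expect_identical(a$truth$outliers, b$truth$outliers)
  c <- small_study(seed = 12)
  expect_false(identical(a$table$abundance, c$table$abundance))
})

test_that("ground-truth index sets are disjoint and in range", {
  tr <- make_ground_truth(small_spec(seed = 3))
  sets <- c(list(tr$background, tr$tissue_markers, tr$drought_responsive,
                 tr$biomass_linked), tr$genotype_markers)
  all_idx <- unlist(sets)
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_true(all(all_idx >= 1 & all_idx <= 80))
  expect_true(all(tr$drought_tissue_specific %in% tr$drought_responsive))
  expect_true(all(tr$k >= 0.16 & tr$k <= 0.67))
})

test_that("biomass follows the allometric power law", {
  spec <- small_spec(seed = 5)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)

  # identity allometry: k = 1, ln b = 0, no noise -> root equals shoot
  tr1 <- truth
  tr1$k[] <- 1; tr1$ln_b[] <- 0
  tr1$drought_shoot_mult[] <- 1; tr1$drought_root_mult[] <- 1
  b1 <- simulate_biomass(design, tr1, noise_sd = 0, seed = 5)
  expect_equal(b1$root_dw_g, b1$shoot_dw_g, tolerance = 1e-12)

  # closed form: k = 0.5, b = 1, shoot = 0.25 -> root = 0.5
  expect_equal(exp(0 + 0.5 * log(0.25)), 0.5)
  tr2 <- tr1; tr2$k[] <- 0.5
  b2 <- simulate_biomass(design, tr2, noise_sd = 0, seed = 5)
  expect_equal(b2$root_dw_g, sqrt(b2$shoot_dw_g), tolerance = 1e-12)

  # noiseless per-accession OLS slopes recover the generating k_i exactly
  b3 <- simulate_biomass(design, truth, noise_sd = 0, seed = 5)
  for (g in unique(b3$genotype)) {
    sub <- b3[b3$genotype == g & b3$regime == "control", ]
    slope <- stats::coef(stats::lm(log(root_dw_g) ~ log(shoot_dw_g), sub))[2]
    expect_equal(unname(slope), unname(truth$k[g]), tolerance = 1e-9)
  }
  expect_true(all(b3$shoot_dw_g > 0 & b3$root_dw_g > 0))
})

test_that("artifact-free tables have no NA and no fence violation in any cell", {
  spec <- small_spec(seed = 7, n_genotypes = 3, n_features = 80)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  sim <- simulate_feature_table(design, truth, missing_rate = 0,
                                outlier_rate = 0, zero_rate = 0, seed = 7)
  ab <- sim$table$abundance
  expect_false(anyNA(ab))
  cells <- interaction(design$genotype, design$regime, design$tissue)
  for (cl in levels(cells)) {
    m <- ab[cells == cl, , drop = FALSE]
    q <- apply(m, 2, stats::quantile, probs = c(0.25, 0.75), type = 7)
    iqr <- q[2, ] - q[1, ]
    expect_true(all(m <= rep(q[2, ] + 3 * iqr, each = nrow(m))))
    expect_true(all(m >= rep(q[1, ] - 3 * iqr, each = nrow(m))))
  }
})

test_that("artifact coordinates are recorded and land inside the table", {
  st <- small_study(seed = 9)
  for (set in list(st$truth$zeros, st$truth$missing, st$truth$outliers)) {
    expect_true(all(set$sample_id %in% st$design$sample_id))
    expect_true(all(set$feature %in% colnames(st$table$abundance)))
  }
  key <- function(d) paste(d$sample_id, d$feature)
  expect_equal(anyDuplicated(c(key(st$truth$zeros), key(st$truth$missing),
                               key(st$truth$outliers))), 0L)
  z <- st$table$abundance[cbind(match(st$truth$zeros$sample_id, st$design$sample_id),
                                match(st$truth$zeros$feature,
                                      colnames(st$table$abundance)))]
  expect_true(all(z == 0))
})

test_that("effect-size ordering is enforced as a precondition", {
  spec <- small_spec(seed = 2)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  expect_error(simulate_feature_table(design, truth,
                                      effect_sizes = list(tissue = 1, genotype = 2,
                                                          regime = 0.5, biomass = 0.5),
                                      seed = 2),
               "configuration error")
})

test_that("zero planted effects give uniform per-feature ANOVA p-values", {
  spec <- design_spec(n_genotypes = 4, n_replicates = 5, n_features = 200,
                      seed = 13)
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  sim <- simulate_feature_table(design, truth,
                                effect_sizes = list(tissue = 1e-9, genotype = 0,
                                                    regime = 0, biomass = 0),
                                missing_rate = 0, outlier_rate = 0,
                                zero_rate = 0, seed = 13)
  lt <- log2_transform(sim$table)
  res <- test_metabolites(lt, "aboveground")
  p <- res$p[res$testable]
  expect_gt(length(p), 500)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  # Holm-significant count under the null is (essentially) zero
  expect_lte(sum(res$significant), 1)
})

test_that("default draw orders pseudo-F as tissue > genotype > regime", {
  # default effects and rates on a reduced design (12 genotypes, 1000
  # features) to keep the check fast; the ordering contract is about the
  # effect sizes, not the table dimensions
  spec <- design_spec(n_genotypes = 12, n_replicates = 5, n_features = 1000,
                      seed = 17)
  st <- synth_study(spec)
  f <- filter_pipeline(st$table, st$blanks)
  lt <- log2_transform(f)
  imp <- impute_pca(lt$abundance, n_components = 5, max_iter = 20)
  pm <- permanova(stats::dist(imp$completed), lt$meta,
                  ~ genotype * tissue * regime, n_perm = 0)
  f_of <- function(term) pm$pseudo_f[pm$term == term]
  expect_gt(f_of("tissue"), f_of("genotype"))
  expect_gt(f_of("genotype"), f_of("regime"))
  # sums of squares order the same way but with genotype far above regime
  ss_of <- function(term) pm$ss[pm$term == term]
  expect_gt(ss_of("tissue"), ss_of("genotype"))
  expect_gt(ss_of("genotype"), ss_of("regime"))
})
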