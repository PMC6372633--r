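# Filtering module: the four canonical steps, the log2 transform, the ANOVA
# presence filter, and the pipeline-level invariants.

test_that("background removal follows the blank/sample mean-ratio rule", {
  ft <- manual_table(g = 2, r = 3, n_feat = 3, fill = 2)
  blanks <- matrix(0, 2, 3, dimnames = list(NULL, colnames(ft$abundance)))

  # all-zero blanks leave the table unchanged
  out <- remove_background(ft, blanks)
  expect_identical(out$abundance, ft$abundance)

  # blank mean equal to sample mean is dropped at threshold 0.5
  blanks[, 2] <- 2
  out <- remove_background(ft, blanks, ratio_threshold = 0.5)
  expect_equal(colnames(out$abundance), colnames(ft$abundance)[-2])
  expect_equal(filter_log(out)[[1]]$removed, "F002")

  # disjoint feature axes are a schema error
  colnames(blanks) <- paste0("X", 1:3)
  expect_error(remove_background(ft, blanks), "schema error")
})

test_that("synthetic background features are exactly the removed set", {
  st <- small_study(seed = 21)
  out <- remove_background(st$table, st$blanks)
  removed <- filter_log(out)[[1]]$removed
  bg_ids <- colnames(st$table$abundance)[st$truth$background]
  expect_setequal(removed, bg_ids)
})

test_that("zeros_to_missing converts exactly the zero cells and is idempotent", {
  ft <- manual_table(g = 1, r = 3, n_feat = 4, fill = 5)
  ft$abundance[cbind(c(1, 2, 3, 4, 5, 6, 7), rep(1:4, length.out = 7))] <- 0
  out <- zeros_to_missing(ft)
  expect_equal(sum(is.na(out$abundance)), 7)
  expect_equal(out$abundance[!is.na(out$abundance)],
               ft$abundance[ft$abundance != 0])
  out2 <- zeros_to_missing(out)
  expect_identical(out2$abundance, out$abundance)

  clean <- manual_table(g = 1, r = 2, n_feat = 2, fill = 3)
  expect_identical(zeros_to_missing(clean)$abundance, clean$abundance)
})

test_that("presence filter keeps a feature iff some cell has >= min_present", {
  ft <- manual_table(g = 2, r = 5, n_feat = 3, fill = 2)
  cells <- interaction(ft$meta$genotype, ft$meta$regime, ft$meta$tissue)
  # feature 1: 5 values in one cell, none elsewhere -> kept
  ft$abundance[, 1] <- NA
  ft$abundance[cells == levels(cells)[1], 1] <- 2
  # feature 2: at most 2 values in every cell -> removed
  ft$abundance[, 2] <- NA
  for (cl in levels(cells)) ft$abundance[which(cells == cl)[1:2], 2] <- 2
  out <- presence_filter(ft)
  expect_true("F001" %in% colnames(out$abundance))
  expect_false("F002" %in% colnames(out$abundance))
  expect_true("F003" %in% colnames(out$abundance))

  # complete table: nothing removed
  full <- manual_table(g = 2, r = 5, n_feat = 4, fill = 1)
  expect_equal(ncol(presence_filter(full)$abundance), 4)

  # brute-force recount over a randomized missingness pattern
  set.seed(31)
  ft2 <- manual_table(g = 3, r = 4, n_feat = 30)
  ft2$abundance[sample(length(ft2$abundance), 900)] <- NA
  out2 <- presence_filter(ft2)
  cells2 <- interaction(ft2$meta$genotype, ft2$meta$regime, ft2$meta$tissue)
  keep_bf <- vapply(seq_len(30), function(j) {
    any(vapply(levels(cells2), function(cl)
      sum(!is.na(ft2$abundance[cells2 == cl, j])) >= 3, TRUE))
  }, TRUE)
  expect_equal(colnames(out2$abundance), colnames(ft2$abundance)[keep_bf])
})

test_that("outlier fences follow hand-computed type-7 quartiles", {
  # one cell {1,2,3,4,100}: Q1 = 2, Q3 = 4, IQR = 2, upper fence = 10
  ft <- manual_table(g = 1, r = 5, n_feat = 1, fill = 1)
  keep <- ft$meta$tissue == "aboveground" & ft$meta$regime == "control"
  ft$abundance[keep, 1] <- c(1, 2, 3, 4, 100)
  ft$abundance[!keep, 1] <- 5
  out <- flag_outliers(ft)
  flagged <- filter_log(out)[[1]]$flagged
  expect_equal(nrow(flagged), 1)
  expect_true(is.na(out$abundance[which(keep)[5], 1]))

  # constant cell: IQR = 0, nothing strictly exceeds the fence
  cft <- manual_table(g = 1, r = 5, n_feat = 2, fill = 5)
  cout <- flag_outliers(cft)
  expect_equal(nrow(filter_log(cout)[[1]]$flagged), 0)
})

test_that("flag_outliers matches a brute-force per-cell recomputation", {
  set.seed(41)
  ft <- manual_table(g = 3, r = 4, n_feat = 40, gen = function(n) rlnorm(n, 2, 1))
  ft$abundance[sample(length(ft$abundance), 150)] <- NA
  out <- flag_outliers(ft)
  cells <- interaction(ft$meta$genotype, ft$meta$regime, ft$meta$tissue)
  bf <- matrix(FALSE, nrow(ft$abundance), ncol(ft$abundance))
  for (cl in levels(cells)) {
    rows <- which(cells == cl)
    for (j in seq_len(ncol(ft$abundance))) {
      v <- ft$abundance[rows, j]
      obs <- v[!is.na(v)]
      if (length(obs) < 1) next
      q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      bf[rows, j] <- !is.na(v) & (v > q[2] + 3 * iqr | v < q[1] - 3 * iqr)
    }
  }
  expect_identical(unname(is.na(out$abundance) & !is.na(ft$abundance)), bf)
})

test_that("log2 transform is elementwise with missing preserved", {
  ft <- manual_table(g = 1, r = 2, n_feat = 2, fill = c(8, 1, 4, 2))
  ft$abundance[2, 2] <- NA
  out <- log2_transform(ft)
  expect_equal(out$abundance[1, 1], 3)
  expect_equal(out$abundance[!is.na(ft$abundance) & ft$abundance == 1][1], 0)
  expect_true(is.na(out$abundance[2, 2]))

  bad <- manual_table(g = 1, r = 2, n_feat = 1, fill = 1)
  bad$abundance[3, 1] <- 0
  expect_error(log2_transform(bad), "non-positive abundance at sample")
})

test_that("ANOVA presence filter counts untestable metabolites per tissue", {
  # complete table: zero removals everywhere
  full <- manual_table(g = 2, r = 3, n_feat = 4, fill = 2)
  res <- anova_presence_filter(full)
  expect_true(all(res$removed == 0))
  expect_true(all(unlist(res$testable)))

  # one value in a regime group makes the metabolite untestable for that
  # genotype (variance undefined)
  ft <- manual_table(g = 2, r = 3, n_feat = 2, fill = 2)
  rows <- ft$meta$genotype == "G01" & ft$meta$regime == "drought" &
    ft$meta$tissue == "aboveground"
  ft$abundance[which(rows)[1:2], 1] <- NA
  res2 <- anova_presence_filter(ft)
  expect_false(res2$testable$aboveground["G01", "F001"])
  expect_true(res2$testable$aboveground["G02", "F001"])
  expect_equal(unname(res2$removed["aboveground"]), 0) # still testable for G02

  # heavy missingness: counts match a direct recount and are seed-stable
  spec <- design_spec(n_genotypes = 3, n_replicates = 4, n_features = 120,
                      seed = 51)
  st <- synth_study(spec)
  design <- st$design; truth <- st$truth
  sim <- simulate_feature_table(design, truth, missing_rate = 0.3, seed = 51)
  lt <- zeros_to_missing(sim$table)
  res3 <- anova_presence_filter(lt)
  for (ti in names(res3$removed)) {
    recount <- sum(colSums(res3$testable[[ti]]) == 0)
    expect_equal(unname(res3$removed[ti]), recount)
    expect_gte(recount, 0)
  }
  sim_b <- simulate_feature_table(design, truth, missing_rate = 0.3, seed = 51)
  res3b <- anova_presence_filter(zeros_to_missing(sim_b$table))
  expect_identical(res3$removed, res3b$removed)
})

test_that("canonical pipeline is idempotent and only ever removes information", {
  st <- small_study(seed = 61)
  f1 <- filter_pipeline(st$table, st$blanks)
  n_nonmiss <- function(t) sum(!is.na(t$abundance))
  # non-missing count non-increasing across every step
  s1 <- remove_background(st$table, st$blanks)
  s2 <- zeros_to_missing(s1)
  s3 <- presence_filter(s2)
  s4 <- flag_outliers(s3)
  counts <- vapply(list(st$table, s1, s2, s3, s4), n_nonmiss, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_identical(s4$abundance, f1$abundance)
  # fixed-point: running the canonical pipeline on its own output changes
  # nothing (cells altered by flagging drop below the n = 5 needed to flag)
  f2 <- filter_pipeline(f1, st$blanks)
  expect_identical(f2$abundance, f1$abundance)
})
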