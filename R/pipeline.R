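# End-to-end orchestration: simulate -> validate -> filter -> allometry ->
# multivariate -> differential -> coherence -> predict, driven by a single
# serializable config with explicit per-stage parameters and one base seed.
# The run report contains every parameter that affects any output and no
# timestamps, so identical configs give byte-identical reports.

#' Per-plant profiles with concatenated tissue features
#'
#' Reshapes a feature table to one row per plant, concatenating the
#' aboveground and belowground feature vectors of the same plant (columns
#' prefixed `ab_` / `be_`).
#'
#' @param table a [feature_table()].
#' @return list with `profiles` (plants x 2*features matrix) and `meta`
#'   (plant-level data.frame: plant_id, genotype, regime, replicate).
#' @export
plant_profiles <- function(table) {
  tissues <- unique(table$meta$tissue)
  stopifnot(length(tissues) == 2L)
  rows1 <- table$meta$tissue == tissues[1]
  rows2 <- table$meta$tissue == tissues[2]
  m1 <- table$abundance[rows1, , drop = FALSE]
  m2 <- table$abundance[rows2, , drop = FALSE]
  pid1 <- table$meta$plant_id[rows1]
  pid2 <- table$meta$plant_id[rows2]
  common <- intersect(pid1, pid2)
  m1 <- m1[match(common, pid1), , drop = FALSE]
  m2 <- m2[match(common, pid2), , drop = FALSE]
  colnames(m1) <- paste0("ab_", colnames(m1))
  colnames(m2) <- paste0("be_", colnames(m2))
  prof <- cbind(m1, m2)
  rownames(prof) <- common
  meta <- unique(table$meta[c("plant_id", "genotype", "regime", "replicate")])
  meta <- meta[match(common, meta$plant_id), ]
  rownames(meta) <- NULL
  list(profiles = prof, meta = meta)
}

#' Build a pipeline configuration
#'
#' @param output_dir directory for all stage outputs.
#' @param seed base seed; every stochastic stage derives a named substream.
#' @param stages named logical list toggling the eight stages (`simulate`,
#'   `validate`, `filter`, `allometry`, `multivariate`, `differential`,
#'   `coherence`, `predict`).
#' @param design list passed to [design_spec()] (`n_genotypes`,
#'   `n_replicates`, `n_features`).
#' @param inputs optional list of existing input paths (`feature`, `blanks`,
#'   `biomass`) used when `simulate` is off.
#' @param params per-stage parameter overrides: `filter` (ratio_threshold,
#'   min_present), `allometry` (chains, iter, warmup), `multivariate`
#'   (n_perm, impute_rank, gamma_perm), `differential` (alpha), `predict`
#'   (n_trees, n_folds). Defaults are scaled for routine runs; raise
#'   `n_perm` to the study value 10000 for final analyses.
#' @param log_level "info" or "quiet".
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1L,
                            stages = list(), design = list(),
                            inputs = list(), params = list(),
                            log_level = "info") {
  stage_names <- c("simulate", "validate", "filter", "allometry",
                   "multivariate", "differential", "coherence", "predict")
  st <- stats::setNames(as.list(rep(TRUE, length(stage_names))), stage_names)
  for (nm in names(stages)) {
    if (!nm %in% stage_names) stop("unknown stage '", nm, "'")
    st[[nm]] <- isTRUE(stages[[nm]])
  }
  dsn <- utils::modifyList(list(n_genotypes = 30L, n_replicates = 5L,
                                n_features = 2897L), design)
  prm <- utils::modifyList(list(
    filter = list(ratio_threshold = 0.5, min_present = 3L),
    allometry = list(chains = 4L, iter = 1000L, warmup = 1000L),
    multivariate = list(n_perm = 999L, impute_rank = 5L, gamma_perm = 1000L),
    differential = list(alpha = 0.01),
    coherence = list(require_purity = TRUE),
    predict = list(n_trees = 300L, n_folds = 5L)
  ), params)
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 stages = st, design = dsn, inputs = inputs, params = prm,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' Configs round-trip through JSON unchanged.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(output_dir = x$output_dir, seed = x$seed,
                  stages = as.list(x$stages), design = as.list(x$design),
                  inputs = as.list(x$inputs), params = lapply(x$params, as.list),
                  log_level = x$log_level)
}

#' Validate pipeline input files
#'
#' Checks the CSV dialects: required columns, factor completeness and weight
#' positivity, with row-level diagnostics.
#'
#' @param paths named list with any of `feature`, `blanks`, `biomass`.
#' @return list with `ok` (logical) and `issues` (character vector naming
#'   file, row/column and problem).
#' @export
validate_inputs <- function(paths) {
  issues <- character(0)
  if (!is.null(paths$feature)) {
    if (!file.exists(paths$feature)) {
      issues <- c(issues, paste0("feature: file not found: ", paths$feature))
    } else {
      df <- tryCatch(utils::read.csv(paths$feature, check.names = FALSE),
                     error = function(e) e)
      if (inherits(df, "error")) {
        issues <- c(issues, paste0("feature: unreadable: ", conditionMessage(df)))
      } else {
        need <- c("plant_id", "genotype", "tissue", "regime", "replicate")
        miss <- setdiff(need, names(df))
        if (length(miss))
          issues <- c(issues, paste0("feature: missing column '", miss, "'"))
        for (col in intersect(need, names(df))) {
          bad <- which(is.na(df[[col]]) | df[[col]] == "")
          if (length(bad))
            issues <- c(issues, paste0("feature: empty ", col, " at row ",
                                       bad[1], " (", length(bad), " total)"))
        }
        featcols <- setdiff(names(df), need)
        vals <- suppressWarnings(as.matrix(df[featcols]))
        storage.mode(vals) <- "double"
        neg <- which(vals < 0, arr.ind = TRUE)
        if (nrow(neg))
          issues <- c(issues, paste0("feature: negative abundance at row ",
                                     neg[1, 1], ", column '",
                                     featcols[neg[1, 2]], "'"))
      }
    }
  }
  if (!is.null(paths$biomass)) {
    if (!file.exists(paths$biomass)) {
      issues <- c(issues, paste0("biomass: file not found: ", paths$biomass))
    } else {
      df <- tryCatch(utils::read.csv(paths$biomass), error = function(e) e)
      if (inherits(df, "error")) {
        issues <- c(issues, paste0("biomass: unreadable: ", conditionMessage(df)))
      } else {
        need <- c("plant_id", "genotype", "regime", "shoot_dw_g", "root_dw_g")
        miss <- setdiff(need, names(df))
        if (length(miss))
          issues <- c(issues, paste0("biomass: missing column '", miss, "'"))
        for (col in intersect(c("shoot_dw_g", "root_dw_g"), names(df))) {
          bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
          if (length(bad))
            issues <- c(issues, paste0("biomass: non-positive ", col,
                                       " at row ", bad[1]))
        }
      }
    }
  }
  if (!is.null(paths$blanks) && !file.exists(paths$blanks))
    issues <- c(issues, paste0("blanks: file not found: ", paths$blanks))
  list(ok = length(issues) == 0L, issues = issues)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in canonical order and writes all stage
#' outputs plus a machine-readable JSON run report (`run_report.json`) under
#' `config$output_dir`. Reruns with the same config are byte-identical for
#' the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, paste0(...))
  say <- function(...) if (!identical(config$log_level, "quiet"))
    message("[metabotyper] ", ...)
  report <- list(package_version = as.character(utils::packageVersion("metabotyper")),
                 seed = config$seed, config = unclass(config), stages = list())
  add_stage <- function(name, info) {
    report$stages[[length(report$stages) + 1L]] <<- c(list(stage = name), info)
  }

  paths <- config$inputs
  table <- NULL; blanks <- NULL; biomass <- NULL; truth <- NULL

  if (isTRUE(config$stages$simulate)) {
    say("simulate")
    spec <- design_spec(n_genotypes = config$design$n_genotypes,
                        n_replicates = config$design$n_replicates,
                        n_features = config$design$n_features,
                        seed = config$seed)
    study <- synth_study(spec)
    table <- study$table; blanks <- study$blanks; biomass <- study$biomass
    truth <- study$truth
    write_feature_csv(table, out("features.csv"))
    write_blank_csv(blanks, out("blanks.csv"))
    write_biomass_csv(biomass, out("biomass.csv"))
    write_ground_truth(truth, out("ground_truth.json"))
    paths <- list(feature = out("features.csv"), blanks = out("blanks.csv"),
                  biomass = out("biomass.csv"))
    add_stage("simulate", list(n_samples = nrow(table$abundance),
                               n_features = ncol(table$abundance),
                               n_plants = nrow(biomass)))
  }

  if (isTRUE(config$stages$validate)) {
    say("validate")
    v <- validate_inputs(paths)
    add_stage("validate", list(ok = v$ok, n_issues = length(v$issues),
                               issues = v$issues))
    if (!v$ok) stop("pipeline aborted at stage 'validate': ",
                    paste(v$issues, collapse = "; "))
  }

  need_table <- any(unlist(config$stages[c("filter", "multivariate",
                                           "differential", "coherence",
                                           "predict")]))
  if (is.null(table) && need_table && !is.null(paths$feature)) {
    table <- read_feature_csv(paths$feature)
    if (!is.null(paths$blanks)) blanks <- read_blank_csv(paths$blanks)
  }
  need_biomass <- any(unlist(config$stages[c("allometry", "predict")]))
  if (is.null(biomass) && need_biomass && !is.null(paths$biomass))
    biomass <- read_biomass_csv(paths$biomass)

  filtered <- NULL
  if (isTRUE(config$stages$filter)) {
    say("filter")
    if (is.null(table)) stop("pipeline aborted at stage 'filter': no feature table")
    filtered <- filter_pipeline(table, blanks,
                                ratio_threshold = config$params$filter$ratio_threshold,
                                min_present = config$params$filter$min_present)
    write_feature_csv(filtered, out("features_filtered.csv"))
    rep <- filter_report(filtered, out("filter_report.json"))
    add_stage("filter", list(steps = rep,
                             n_features_out = ncol(filtered$abundance)))
  } else filtered <- table

  if (isTRUE(config$stages$allometry)) {
    say("allometry")
    if (is.null(biomass)) stop("pipeline aborted at stage 'allometry': no biomass table")
    pa <- config$params$allometry
    coefs <- list(); conv <- list()
    for (rg in unique(biomass$regime)) {
      fit <- fit_allometry_bhm(biomass[biomass$regime == rg, ],
                               chains = pa$chains, iter = pa$iter,
                               warmup = pa$warmup,
                               seed = substream(config$seed, paste0("allo_", rg)))
      smry <- fit$summary
      smry$regime <- rg
      coefs[[rg]] <- smry
      conv[[rg]] <- fit$converged
      utils::write.csv(smry, out("allometry_", rg, ".csv"), row.names = FALSE)
    }
    rmf <- compute_rmf(biomass)
    utils::write.csv(rmf, out("rmf.csv"), row.names = FALSE)
    dt <- test_drought_biomass(biomass)
    utils::write.csv(dt, out("drought_biomass_tests.csv"), row.names = FALSE)
    add_stage("allometry", list(converged = conv,
                                k_range = range(do.call(rbind, coefs)$k_mean),
                                n_significant_drought =
                                  sum(dt$tested & dt$p < 0.05, na.rm = TRUE)))
  }

  log2t <- NULL
  completed <- NULL
  if (any(unlist(config$stages[c("multivariate", "differential", "coherence",
                                 "predict")]))) {
    log2t <- log2_transform(filtered)
    pmv <- config$params$multivariate
    imp <- impute_pca(log2t$abundance, n_components = pmv$impute_rank,
                      max_iter = 50L)
    completed <- imp$completed
  }

  if (isTRUE(config$stages$multivariate)) {
    say("multivariate")
    pmv <- config$params$multivariate
    d <- stats::dist(completed)
    pm <- permanova(d, log2t$meta, ~ genotype * tissue * regime,
                    n_perm = pmv$n_perm,
                    seed = substream(config$seed, "permanova"))
    utils::write.csv(as.data.frame(pm), out("permanova.csv"), row.names = FALSE)
    # genotype-averaged control dendrograms per tissue + Baker's gamma
    trees <- list()
    for (ti in unique(log2t$meta$tissue)) {
      rows <- log2t$meta$tissue == ti & log2t$meta$regime == "control"
      sub <- completed[rows, , drop = FALSE]
      g <- factor(log2t$meta$genotype[rows])
      prof <- do.call(rbind, lapply(levels(g), function(lv)
        colMeans(sub[g == lv, , drop = FALSE])))
      rownames(prof) <- levels(g)
      tr <- hcluster_ward_squared(stats::dist(prof))
      trees[[ti]] <- tr
      write_tree_newick(tr, out("dendrogram_", ti, ".nwk"))
    }
    gamma <- if (length(trees) == 2L)
      gamma_permutation_test(trees[[1]], trees[[2]], n_perm = pmv$gamma_perm,
                             seed = substream(config$seed, "gamma"))
      else NULL
    pc <- pca(completed, scale = TRUE)
    utils::write.csv(data.frame(sample_id = rownames(pc$scores),
                                pc$scores[, seq_len(min(5, ncol(pc$scores)))]),
                     out("pca_scores.csv"), row.names = FALSE)
    add_stage("multivariate", list(
      permanova = stats::setNames(as.list(pm$pseudo_f[seq_len(nrow(pm) - 2)]),
                                  pm$term[seq_len(nrow(pm) - 2)]),
      permanova_p = stats::setNames(as.list(pm$p[seq_len(nrow(pm) - 2)]),
                                    pm$term[seq_len(nrow(pm) - 2)]),
      bakers_gamma = if (!is.null(gamma)) gamma$gamma else NA,
      gamma_p = if (!is.null(gamma)) gamma$p else NA,
      pc1_var_frac = pc$var_frac[1],
      imputation_converged = imp$converged))
  }

  if (isTRUE(config$stages$differential)) {
    say("differential")
    apf <- anova_presence_filter(log2t)
    res <- do.call(rbind, lapply(unique(log2t$meta$tissue), function(ti)
      test_metabolites(log2t, ti, testable = apf$testable[[ti]],
                       alpha = config$params$differential$alpha)))
    utils::write.csv(res, out("differential.csv"), row.names = FALSE)
    counts <- count_significant(res)
    utils::write.csv(counts, out("differential_counts.csv"), row.names = FALSE)
    add_stage("differential", list(
      anova_filter_removed = as.list(apf$removed),
      n_significant_total = sum(res$significant)))
  }

  if (isTRUE(config$stages$coherence)) {
    say("coherence")
    ctab <- feature_table_from_parts(completed, log2t$meta)
    pp <- plant_profiles(ctab)
    coh <- list()
    for (rg in unique(pp$meta$regime)) {
      rows <- pp$meta$regime == rg
      tr <- hcluster_ward_squared(stats::dist(pp$profiles[rows, , drop = FALSE]))
      k <- length(unique(pp$meta$genotype))
      cl <- cut_tree(tr, k)
      tab <- build_coherence_table(cl, pp$meta$genotype[rows])
      cf <- coherence_fraction(tab,
                               require_purity = config$params$coherence$require_purity)
      utils::write.csv(coherence_bubble_data(tab),
                       out("coherence_bubble_", rg, ".csv"), row.names = FALSE)
      coh[[rg]] <- cf$fraction
    }
    jsonlite::write_json(coh, out("coherence.json"), auto_unbox = TRUE, digits = NA)
    add_stage("coherence", list(fraction = coh))
  }

  if (isTRUE(config$stages$predict)) {
    say("predict")
    if (is.null(biomass)) stop("pipeline aborted at stage 'predict': no biomass table")
    pp <- plant_profiles(feature_table_from_parts(completed, log2t$meta))
    common <- intersect(rownames(pp$profiles), biomass$plant_id)
    X <- pp$profiles[common, , drop = FALSE]
    gset <- pp$meta$genotype[match(common, pp$meta$plant_id)]
    y <- biomass$shoot_dw_g[match(common, biomass$plant_id)]
    ppred <- config$params$predict
    fit <- fit_biomass_predictor(X, gset, y, n_folds = ppred$n_folds,
                                 n_trees = ppred$n_trees,
                                 seed = substream(config$seed, "predict"))
    abl <- ablation_rmse_delta(X, gset, startsWith(colnames(X), "be_"), y,
                               n_folds = ppred$n_folds, n_trees = ppred$n_trees,
                               seed = substream(config$seed, "predict"))
    imp_order <- order(fit$importance, decreasing = TRUE)
    utils::write.csv(data.frame(feature = names(fit$importance)[imp_order],
                                importance = fit$importance[imp_order]),
                     out("rf_importance.csv"), row.names = FALSE)
    pred_rep <- list(cv_rmse_g = fit$cv_rmse, best_mtry = fit$best_mtry,
                     ablation_pct_increase = abl$pct_increase)
    jsonlite::write_json(pred_rep, out("predict.json"), auto_unbox = TRUE,
                         digits = NA)
    add_stage("predict", pred_rep)
  }

  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  say("done: ", length(report$stages), " stage(s)")
  invisible(report)
}

# Rebuild a feature_table around an already-transformed matrix (used for the
# imputed log2 matrix, which may contain legitimate negatives).
feature_table_from_parts <- function(abundance, meta) {
  structure(list(abundance = abundance, meta = meta, log = list()),
            class = "feature_table")
}
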