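# Metabotype -> biomass prediction: a cross-validated random-forest regressor
# over metabolite features plus genotype one-hot indicators (so metabolites
# must explain biomass beyond genotypic effects), tuned over a small mtry
# grid, with out-of-fold permutation importance and the feature-group
# ablation statistic (percent RMSE increase when a named group is removed
# under identical folds).

rf_design <- function(features, genotype_indicators) {
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("X", seq_len(ncol(features)))
  if (!is.null(genotype_indicators)) {
    g <- factor(genotype_indicators)
    onehot <- stats::model.matrix(~ g - 1)
    colnames(onehot) <- paste0("genotype_", levels(g))
    cbind(onehot, features)
  } else features
}

make_folds <- function(n, n_folds, seed) {
  local_seed(substream(seed, "cv_folds"), {
    sample(rep_len(seq_len(n_folds), n))
  })
}

#' Cross-validated random-forest biomass predictor
#'
#' Tunes mtry over `{sqrt(p), p/3, p/10}` by `n_folds`-fold cross-validation
#' (the reported RMSE is the average of the per-fold RMSEs for the selected
#' mtry), computes out-of-fold permutation importance for every column, and
#' refits a final forest on the full data.
#'
#' @param features numeric matrix of predictors (samples x features); no
#'   missing values (impute upstream).
#' @param genotype_indicators genotype factor per sample, expanded to one-hot
#'   columns (`NULL` to omit).
#' @param target numeric response (a dry weight in grams).
#' @param n_folds folds (study default 5).
#' @param n_trees trees per forest (default 500).
#' @param mtry_grid candidate mtry values; default `{sqrt(p), p/3, p/10}`.
#' @param min_node minimal node size (default 5).
#' @param seed integer seed; fixes folds, bootstraps and permutations.
#' @param importance compute permutation importance (default TRUE).
#' @return a `biomass_predictor` list: `cv_rmse`, `cv_rmse_by_mtry`,
#'   `best_mtry`, `importance` (mean out-of-fold MSE increase per column),
#'   `folds`, `forest`, `seed`.
#' @export
fit_biomass_predictor <- function(features, genotype_indicators, target,
                                  n_folds = 5L, n_trees = 500L,
                                  mtry_grid = NULL, min_node = 5L, seed = 1L,
                                  importance = TRUE) {
  X <- rf_design(features, genotype_indicators)
  if (anyNA(X) || anyNA(target)) stop("missing values; impute upstream")
  n <- nrow(X)
  if (n < n_folds) stop("fewer samples (", n, ") than folds (", n_folds, ")")
  p <- ncol(X)
  if (is.null(mtry_grid))
    mtry_grid <- sort(unique(pmax(1L, round(c(sqrt(p), p / 3, p / 10)))))
  folds <- make_folds(n, n_folds, seed)

  fold_rmse <- matrix(NA_real_, n_folds, length(mtry_grid),
                      dimnames = list(NULL, paste0("mtry", mtry_grid)))
  imp_acc <- matrix(0, n_folds, p, dimnames = list(NULL, colnames(X)))
  for (fi in seq_len(n_folds)) {
    tr <- folds != fi; te <- !tr
    for (mi in seq_along(mtry_grid)) {
      fit <- local_seed(substream(seed, paste0("rf_f", fi, "m", mi)), {
        rf_fit_cpp(X[tr, , drop = FALSE], target[tr], n_trees,
                   mtry_grid[mi], min_node)
      })
      pred <- rf_predict_cpp(fit, X[te, , drop = FALSE])
      fold_rmse[fi, mi] <- sqrt(mean((pred - target[te])^2))
    }
  }
  cv_by_mtry <- colMeans(fold_rmse)
  best_i <- which.min(cv_by_mtry)
  best_mtry <- mtry_grid[best_i]
  cv_rmse <- cv_by_mtry[best_i]

  imp <- NULL
  if (importance) {
    for (fi in seq_len(n_folds)) {
      tr <- folds != fi; te <- !tr
      fit <- local_seed(substream(seed, paste0("rf_f", fi, "m", best_i)), {
        rf_fit_cpp(X[tr, , drop = FALSE], target[tr], n_trees,
                   best_mtry, min_node)
      })
      Xte <- X[te, , drop = FALSE]
      base_mse <- mean((rf_predict_cpp(fit, Xte) - target[te])^2)
      local_seed(substream(seed, paste0("perm_imp", fi)), {
        for (j in seq_len(p)) {
          Xp <- Xte
          Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
          imp_acc[fi, j] <- mean((rf_predict_cpp(fit, Xp) - target[te])^2) - base_mse
        }
      })
    }
    imp <- colMeans(imp_acc)
  }

  final <- local_seed(substream(seed, "rf_final"), {
    rf_fit_cpp(X, target, n_trees, best_mtry, min_node)
  })
  structure(list(cv_rmse = unname(cv_rmse), cv_rmse_by_mtry = cv_by_mtry,
                 best_mtry = best_mtry, importance = imp, folds = folds,
                 n_trees = n_trees, min_node = min_node, forest = final,
                 seed = seed),
            class = "biomass_predictor")
}

#' @export
print.biomass_predictor <- function(x, ...) {
  cat("<biomass_predictor> CV RMSE = ", signif(x$cv_rmse, 4),
      " g | mtry = ", x$best_mtry, " | trees = ", x$n_trees, "\n", sep = "")
  if (!is.null(x$importance)) {
    top <- sort(x$importance, decreasing = TRUE)[seq_len(min(5, length(x$importance)))]
    cat("  top importance:", paste(names(top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percent RMSE increase when a feature group is removed
#'
#' Refits the predictor without the masked feature group under identical
#' folds and seed, and reports
#' `100 * (RMSE_ablated - RMSE_baseline) / RMSE_baseline`.
#'
#' @param features numeric feature matrix.
#' @param genotype_indicators genotype factor (or `NULL`).
#' @param group_mask logical over feature columns: `TRUE` marks the group to
#'   remove. Must be a nonempty proper subset.
#' @param target numeric response.
#' @param n_folds,n_trees,min_node,seed as in [fit_biomass_predictor()].
#' @return an `ablation_result` list: `baseline_rmse`, `ablated_rmse`,
#'   `pct_increase`, `group_size`.
#' @export
ablation_rmse_delta <- function(features, genotype_indicators, group_mask,
                                target, n_folds = 5L, n_trees = 500L,
                                min_node = 5L, seed = 1L) {
  features <- as.matrix(features)
  group_mask <- as.logical(group_mask)
  if (length(group_mask) != ncol(features))
    stop("group_mask length must match the feature count")
  if (!any(group_mask) || all(group_mask))
    stop("group_mask must select a nonempty proper subset of features")
  base <- fit_biomass_predictor(features, genotype_indicators, target,
                                n_folds = n_folds, n_trees = n_trees,
                                min_node = min_node, seed = seed,
                                importance = FALSE)
  abl <- fit_biomass_predictor(features[, !group_mask, drop = FALSE],
                               genotype_indicators, target,
                               n_folds = n_folds, n_trees = n_trees,
                               min_node = min_node, seed = seed,
                               importance = FALSE)
  structure(list(baseline_rmse = base$cv_rmse, ablated_rmse = abl$cv_rmse,
                 pct_increase = 100 * (abl$cv_rmse - base$cv_rmse) / base$cv_rmse,
                 group_size = sum(group_mask), seed = seed),
            class = "ablation_result")
}
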