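# Four-step metabolomics feature-table filter plus the log2 transform and the
# ANOVA presence filter. The canonical order is:
#   background removal -> zeros to missing -> presence filter -> outlier nulling
# Fences use type-7 quartiles (linear interpolation between order statistics)
# with strict inequalities: upper outlier iff value > Q3 + 3*IQR, lower iff
# value < Q1 - 3*IQR, computed per feature within each genotype x regime x
# tissue cell.

#' Outlier fence rule
#'
#' @param lower_mult,upper_mult fence multipliers (both 3 by default).
#' @return an `outlier_rule` list.
#' @export
outlier_rule <- function(lower_mult = 3, upper_mult = 3) {
  stopifnot(lower_mult >= 0, upper_mult >= 0)
  structure(list(lower_mult = lower_mult, upper_mult = upper_mult),
            class = "outlier_rule")
}

#' Remove blank-derived background features
#'
#' Drops every feature whose mean blank abundance is at least
#' `ratio_threshold` times its mean sample abundance.
#'
#' @param table a [feature_table()].
#' @param blanks numeric matrix of blank samples over the same feature axis.
#' @param ratio_threshold blank/sample mean-abundance ratio above which a
#'   feature is considered background; default 0.5.
#' @return the filtered [feature_table()] with the drop list logged.
#' @export
remove_background <- function(table, blanks, ratio_threshold = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  blanks <- as.matrix(blanks)
  feats <- colnames(table$abundance)
  if (is.null(colnames(blanks)) || !length(intersect(feats, colnames(blanks))))
    stop("schema error: blanks do not share the feature axis of the table")
  if (!all(feats %in% colnames(blanks)))
    stop("schema error: blanks are missing ", sum(!feats %in% colnames(blanks)),
         " features of the table")
  blank_mean <- colMeans(blanks[, feats, drop = FALSE], na.rm = TRUE)
  sample_mean <- colMeans(table$abundance, na.rm = TRUE)
  drop <- blank_mean >= ratio_threshold * sample_mean
  drop[is.na(drop)] <- FALSE
  table$abundance <- table$abundance[, !drop, drop = FALSE]
  ft_append_log(table, list(step = "remove_background",
                            ratio_threshold = ratio_threshold,
                            removed = feats[drop]))
}

#' Convert exact zeros to missing values
#'
#' @param table a [feature_table()].
#' @return the table with every exact-zero cell set to `NA`; idempotent.
#' @export
zeros_to_missing <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  zero <- !is.na(table$abundance) & table$abundance == 0
  table$abundance[zero] <- NA_real_
  ft_append_log(table, list(step = "zeros_to_missing", n_zeroed = sum(zero)))
}

#' Cell-factor presence filter
#'
#' A feature is removed iff no genotype x regime x tissue cell holds at least
#' `min_present` non-missing values (one qualifying cell suffices to keep it).
#'
#' @param table a [feature_table()].
#' @param min_present minimum non-missing values in at least one cell.
#' @return the filtered table with the removal list logged.
#' @export
presence_filter <- function(table, min_present = 3L) {
  stopifnot(inherits(table, "feature_table"))
  if (ncol(table$abundance) == 0L || nrow(table$abundance) == 0L)
    stop("schema error: empty table")
  cells <- ft_cells(table)
  present <- !is.na(table$abundance)
  max_cell <- Reduce(pmax, lapply(levels(cells), function(cl)
    colSums(present[cells == cl, , drop = FALSE])))
  keep <- max_cell >= min_present
  removed <- colnames(table$abundance)[!keep]
  table$abundance <- table$abundance[, keep, drop = FALSE]
  ft_append_log(table, list(step = "presence_filter", min_present = min_present,
                            removed = removed))
}

#' Null 3-IQR outliers per cell factor
#'
#' Per feature and genotype x regime x tissue cell, computes type-7 quartiles
#' over the non-missing values and replaces strict fence violations
#' (`> Q3 + upper_mult*IQR` or `< Q1 - lower_mult*IQR`) with missing values.
#' Cells with fewer than four values still get quartiles (fences there can
#' never flag the extremum; see the methods vignette).
#'
#' @param table a [feature_table()].
#' @param rule an [outlier_rule()].
#' @return the table with outliers nulled; per-cell counts and flagged
#'   coordinates are logged.
#' @export
flag_outliers <- function(table, rule = outlier_rule()) {
  stopifnot(inherits(table, "feature_table"), inherits(rule, "outlier_rule"))
  cells <- ft_cells(table)
  ab <- table$abundance
  flagged <- list()
  per_cell <- stats::setNames(integer(nlevels(cells)), levels(cells))
  for (cl in levels(cells)) {
    rows <- which(cells == cl)
    m <- ab[rows, , drop = FALSE]
    n <- length(rows)
    if (n < 2L) next
    counts <- colSums(!is.na(m))
    m_inf <- m
    m_inf[is.na(m_inf)] <- Inf # sentinel keeps NA at the bottom of each column
    srt <- matrix(m_inf[order(col(m_inf), m_inf)], nrow = n)
    q1 <- colwise_type7(srt, counts, 0.25)
    q3 <- colwise_type7(srt, counts, 0.75)
    iqr <- q3 - q1
    up <- q3 + rule$upper_mult * iqr
    lo <- q1 - rule$lower_mult * iqr
    viol <- (m > rep(up, each = n)) | (m < rep(lo, each = n))
    viol[is.na(viol)] <- FALSE
    if (any(viol)) {
      idx <- which(viol, arr.ind = TRUE)
      flagged[[cl]] <- data.frame(
        sample_id = table$meta$sample_id[rows[idx[, 1]]],
        feature = colnames(ab)[idx[, 2]])
      ab[rows, ][viol] <- NA_real_
    }
    per_cell[cl] <- sum(viol)
  }
  table$abundance <- ab
  flagged_df <- if (length(flagged)) do.call(rbind, c(flagged, make.row.names = FALSE))
                else data.frame(sample_id = character(), feature = character())
  ft_append_log(table, list(step = "flag_outliers", rule = unclass(rule),
                            nulled_per_cell = as.list(per_cell),
                            flagged = flagged_df))
}

#' Log2-transform abundances
#'
#' @param table a [feature_table()].
#' @param pseudocount added before taking logs; with the default 0 every
#'   non-missing value must be strictly positive (guaranteed after the
#'   canonical filter pipeline).
#' @return the transformed table; missing values are preserved.
#' @export
log2_transform <- function(table, pseudocount = 0) {
  stopifnot(inherits(table, "feature_table"))
  bad <- which(!is.na(table$abundance) & table$abundance + pseudocount <= 0,
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-positive abundance at sample '",
         rownames(table$abundance)[bad[1, 1]], "', feature '",
         colnames(table$abundance)[bad[1, 2]],
         "' cannot be log2-transformed with pseudocount ", pseudocount)
  }
  table$abundance <- log2(table$abundance + pseudocount)
  # a log2 table may legitimately contain negative values; flag it so the
  # constructor invariant is not re-applied downstream
  attr(table$abundance, "scale") <- "log2"
  ft_append_log(table, list(step = "log2_transform", pseudocount = pseudocount))
}

#' ANOVA presence filter (testability per genotype)
#'
#' Per tissue, a metabolite is testable for genotype g iff both its control
#' and drought groups hold at least `min_per_group` non-missing values (two
#' points are needed to estimate a within-group variance). The per-tissue
#' removal count is the number of metabolites testable for no genotype.
#'
#' @param table a [feature_table()].
#' @param min_per_group minimum non-missing values per regime x genotype
#'   group; default 2.
#' @return list with `table` (testability recorded in the log), `removed`
#'   (named per-tissue counts) and `testable` (per tissue, genotype x feature
#'   logical matrix).
#' @export
anova_presence_filter <- function(table, min_per_group = 2L) {
  stopifnot(inherits(table, "feature_table"))
  tissues <- unique(table$meta$tissue)
  genotypes <- unique(table$meta$genotype)
  regimes <- unique(table$meta$regime)
  testable <- list()
  removed <- stats::setNames(integer(length(tissues)), tissues)
  for (ti in tissues) {
    t_rows <- table$meta$tissue == ti
    tm <- matrix(FALSE, length(genotypes), ncol(table$abundance),
                 dimnames = list(genotypes, colnames(table$abundance)))
    for (g in genotypes) {
      ok <- rep(TRUE, ncol(table$abundance))
      for (r in regimes) {
        rows <- t_rows & table$meta$genotype == g & table$meta$regime == r
        ok <- ok & colSums(!is.na(table$abundance[rows, , drop = FALSE])) >= min_per_group
      }
      tm[g, ] <- ok
    }
    testable[[ti]] <- tm
    removed[ti] <- sum(colSums(tm) == 0L)
  }
  table <- ft_append_log(table, list(step = "anova_presence_filter",
                                     min_per_group = min_per_group,
                                     removed = as.list(removed)))
  list(table = table, removed = removed, testable = testable)
}

#' Run the canonical filter pipeline
#'
#' Background removal, zero-to-missing conversion, cell-factor presence
#' filtering and 3-IQR outlier nulling, in that order. Re-running the
#' pipeline on its own output is a no-op (see the methods vignette for why
#' the outlier step cannot re-flag).
#'
#' @param table a [feature_table()].
#' @param blanks blank-sample matrix (skipped when `NULL`).
#' @param ratio_threshold passed to [remove_background()].
#' @param min_present passed to [presence_filter()].
#' @param rule passed to [flag_outliers()].
#' @return the filtered [feature_table()]; the log holds one record per step.
#' @export
filter_pipeline <- function(table, blanks = NULL, ratio_threshold = 0.5,
                            min_present = 3L, rule = outlier_rule()) {
  if (!is.null(blanks)) table <- remove_background(table, blanks, ratio_threshold)
  table <- zeros_to_missing(table)
  table <- presence_filter(table, min_present)
  flag_outliers(table, rule)
}

#' JSON filter report
#'
#' Summarizes the provenance log of a filtered table: features removed per
#' step and cells nulled per step.
#'
#' @param table a filtered [feature_table()].
#' @param path optional path; when given the report is written as JSON.
#' @return the report list, invisibly when written to disk.
#' @export
filter_report <- function(table, path = NULL) {
  rep <- lapply(filter_log(table), function(rec) {
    out <- list(step = rec$step)
    if (!is.null(rec$removed)) out$n_removed <- length(rec$removed)
    if (!is.null(rec$n_zeroed)) out$n_zeroed <- rec$n_zeroed
    if (!is.null(rec$nulled_per_cell)) {
      out$n_nulled <- sum(unlist(rec$nulled_per_cell))
      out$nulled_per_cell <- rec$nulled_per_cell
    }
    out
  })
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
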