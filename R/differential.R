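# Per-genotype drought-vs-control metabolite tests on the log2 scale:
# two-group one-way ANOVA (pooled-variance F, identical to the squared
# pooled t), Holm step-down correction within each genotype x tissue family,
# log-fold changes as differences of group means, and a heatmap-ready
# per-metabolite z-standardised matrix with a significance mask.

#' Per-genotype two-group ANOVA of drought vs control
#'
#' @param table a log2-transformed, filtered [feature_table()].
#' @param tissue tissue to test (one level of the metadata `tissue` column).
#' @param testable optional genotype x feature logical matrix from
#'   [anova_presence_filter()]; combinations with fewer than 2 values per
#'   group are flagged untestable regardless.
#' @param alpha family-wise significance level (study default 0.01).
#' @param control,drought regime labels.
#' @return a `differential_result` data.frame: `tissue, genotype, metabolite,
#'   lfc, f, p, p_holm, testable, significant`. Holm families are all
#'   testable metabolites within one genotype x tissue.
#' @export
test_metabolites <- function(table, tissue, testable = NULL, alpha = 0.01,
                             control = "control", drought = "drought") {
  stopifnot(inherits(table, "feature_table"))
  rows_t <- table$meta$tissue == tissue
  if (!any(rows_t)) stop("tissue '", tissue, "' not present")
  feats <- colnames(table$abundance)
  out <- list()
  for (g in unique(table$meta$genotype)) {
    mc <- table$abundance[rows_t & table$meta$genotype == g &
                            table$meta$regime == control, , drop = FALSE]
    md <- table$abundance[rows_t & table$meta$genotype == g &
                            table$meta$regime == drought, , drop = FALSE]
    n1 <- colSums(!is.na(mc)); n2 <- colSums(!is.na(md))
    m1 <- colMeans(mc, na.rm = TRUE); m2 <- colMeans(md, na.rm = TRUE)
    v1 <- apply(mc, 2, stats::var, na.rm = TRUE)
    v2 <- apply(md, 2, stats::var, na.rm = TRUE)
    ok <- n1 >= 2L & n2 >= 2L
    if (!is.null(testable)) ok <- ok & testable[g, feats]
    df <- n1 + n2 - 2L
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    lfc <- m2 - m1
    fstat <- ifelse(sp2 > 0, lfc^2 / (sp2 * (1 / n1 + 1 / n2)), Inf)
    p <- ifelse(sp2 > 0, stats::pf(fstat, 1, df, lower.tail = FALSE),
                ifelse(lfc == 0, 1, 0))
    fstat[!is.na(sp2) & sp2 == 0 & !is.na(lfc) & lfc == 0] <- 0
    p[!ok] <- NA_real_
    lfc[!ok] <- NA_real_
    fstat[!ok] <- NA_real_
    p_holm <- rep(NA_real_, length(p))
    p_holm[ok] <- holm_adjust(p[ok])
    out[[g]] <- data.frame(tissue = tissue, genotype = g, metabolite = feats,
                           lfc = lfc, f = fstat, p = p, p_holm = p_holm,
                           testable = ok,
                           significant = !is.na(p_holm) & p_holm <= alpha)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(res, "alpha") <- alpha
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Holm step-down adjustment
#'
#' Sorts p-values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity, caps at 1 and restores the original order. Never less than
#' the raw p and never more than Bonferroni.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA allowed and
#'   returned as NA without counting toward the family size).
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(pvals)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  res <- rep(NA_real_, length(pvals))
  res[ok] <- out
  res
}

#' Heatmap-ready standardized log-fold-change matrix
#'
#' Rows are metabolites, columns genotypes; each row is z-standardized
#' (mean 0, SD 1 with the n-1 convention) across genotypes. Zero-SD rows are
#' set to zero and flagged. The mask marks Holm-significant cells.
#'
#' @param diff a `differential_result` for a single tissue (or filtered to
#'   one via `tissue`).
#' @param tissue optional tissue to select when `diff` spans several.
#' @return list with `z` (matrix), `mask` (logical matrix), `flagged`
#'   (zero-SD metabolites).
#' @export
logfold_heatmap_matrix <- function(diff, tissue = NULL) {
  if (!is.null(tissue)) diff <- diff[diff$tissue == tissue, ]
  if (length(unique(diff$tissue)) > 1L)
    stop("diff spans several tissues; pass `tissue`")
  if (length(unique(diff$genotype)) < 2L)
    stop("need log-fold changes for at least 2 genotypes")
  z <- matrix(NA_real_, length(unique(diff$metabolite)),
              length(unique(diff$genotype)),
              dimnames = list(sort(unique(diff$metabolite)),
                              sort(unique(diff$genotype))))
  z[cbind(match(diff$metabolite, rownames(z)),
          match(diff$genotype, colnames(z)))] <- diff$lfc
  mask <- matrix(FALSE, nrow(z), ncol(z), dimnames = dimnames(z))
  mask[cbind(match(diff$metabolite, rownames(z)),
             match(diff$genotype, colnames(z)))] <- diff$significant
  mu <- rowMeans(z, na.rm = TRUE)
  s <- apply(z, 1, stats::sd, na.rm = TRUE)
  flagged <- rownames(z)[!is.na(s) & s == 0]
  zz <- (z - mu) / ifelse(is.na(s) | s == 0, 1, s)
  zz[!is.na(s) & s == 0 & !is.na(z)] <- 0
  list(z = zz, mask = mask, flagged = flagged)
}

#' Significant-metabolite counts per genotype and tissue
#'
#' @param diff a `differential_result`.
#' @return data.frame `tissue, genotype, n_significant`.
#' @export
count_significant <- function(diff) {
  stats::aggregate(list(n_significant = diff$significant),
                   by = list(tissue = diff$tissue, genotype = diff$genotype),
                   FUN = sum)
}
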