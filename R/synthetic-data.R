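# Ground-truthed synthetic study generator.
#
# Emulates a factorial metabolomics + biomass study: n_genotypes accessions x
# 2 tissues x 2 water regimes x n_replicates plants, a feature table with
# planted tissue / genotype / drought / biomass-linked effects, blank samples
# carrying background features, and injected zeros, missing values and extreme
# outliers whose coordinates are recorded as ground truth.

#' Study design specification
#'
#' @param n_genotypes number of accessions (>= 2); default 30.
#' @param n_replicates plants per genotype x regime cell (>= 2); default 5.
#' @param tissues two tissue labels.
#' @param regimes two water-regime labels; the second is treated as the
#'   stressed (drought) level.
#' @param n_features number of metabolite features; default 2897.
#' @param seed integer seed that fully determines all generated outputs.
#' @return a `design_spec` list.
#' @export
design_spec <- function(n_genotypes = 30L, n_replicates = 5L,
                        tissues = c("aboveground", "belowground"),
                        regimes = c("control", "drought"),
                        n_features = 2897L, seed = 1L) {
  n_genotypes <- as.integer(n_genotypes)
  n_replicates <- as.integer(n_replicates)
  n_features <- as.integer(n_features)
  if (is.na(n_genotypes) || n_genotypes < 2L)
    stop("configuration error: n_genotypes must be >= 2")
  if (is.na(n_replicates) || n_replicates < 2L)
    stop("configuration error: n_replicates must be >= 2")
  if (is.na(n_features) || n_features < 1L)
    stop("configuration error: n_features must be >= 1")
  if (length(tissues) != 2L || length(regimes) != 2L)
    stop("configuration error: exactly two tissues and two regimes are required")
  structure(list(n_genotypes = n_genotypes, n_replicates = n_replicates,
                 tissues = tissues, regimes = regimes,
                 n_features = n_features, seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate the sample metadata for a design
#'
#' One record per plant per tissue; every genotype x regime cell holds exactly
#' `n_replicates` plants. Purely deterministic (no randomness is needed for
#' the layout itself).
#'
#' @param spec a [design_spec()].
#' @return data.frame with columns `sample_id, plant_id, genotype, tissue,
#'   regime, replicate`.
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  genotypes <- sprintf("G%02d", seq_len(spec$n_genotypes))
  plants <- expand.grid(replicate = seq_len(spec$n_replicates),
                        regime = spec$regimes, genotype = genotypes,
                        stringsAsFactors = FALSE)
  plants$plant_id <- sprintf("%s_%s_r%d", plants$genotype,
                             substr(plants$regime, 1, 1), plants$replicate)
  design <- merge(plants, data.frame(tissue = spec$tissues), by = NULL)
  design <- design[order(design$genotype, design$regime, design$replicate,
                         design$tissue), ]
  design$sample_id <- paste(design$plant_id, substr(design$tissue, 1, 2), sep = "_")
  rownames(design) <- NULL
  design[c("sample_id", "plant_id", "genotype", "tissue", "regime", "replicate")]
}

#' Draw the ground truth of a synthetic study
#'
#' Per-accession allometry coefficients (ln b_i uniform on [-2.1, -1.4], k_i
#' uniform on [0.16, 0.67], matching the span of allometric coefficients the
#' package targets), per-accession drought biomass multipliers (root 0.76-2.23,
#' i.e. -24% to +123%; shoot 0.7-1.3), and disjoint planted feature index
#' sets: background (in blanks), tissue markers, per-genotype markers,
#' drought-responsive (half tissue-specific) and biomass-linked features.
#'
#' @param spec a [design_spec()].
#' @return a `ground_truth` list; artifact coordinates are filled in later by
#'   [simulate_feature_table()].
#' @export
make_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  ng <- spec$n_genotypes
  nf <- spec$n_features
  local_seed(substream(spec$seed, "truth"), {
    genotypes <- sprintf("G%02d", seq_len(ng))
    ln_b <- stats::runif(ng, -2.1, -1.4)
    k <- stats::runif(ng, 0.16, 0.67)
    shoot_meanlog <- stats::runif(ng, log(0.15), log(0.45))
    shoot_mult <- stats::runif(ng, 0.7, 1.3)
    root_mult <- stats::runif(ng, 0.76, 2.23)
    names(ln_b) <- names(k) <- names(shoot_meanlog) <- genotypes
    names(shoot_mult) <- names(root_mult) <- genotypes

    n_bg <- max(2L, round(0.02 * nf))
    n_tis <- max(2L, round(0.10 * nf))
    m_per_g <- max(1L, round(0.12 * nf / ng))
    n_dr <- max(2L, round(0.035 * nf))
    n_biom <- max(1L, round(0.01 * nf))
    need <- n_bg + n_tis + m_per_g * ng + n_dr + n_biom
    if (need > nf)
      stop("configuration error: n_features too small for the planted ",
           "effect sets (need >= ", need, ")")
    pool <- sample.int(nf, need)
    take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
    background <- sort(take(n_bg))
    tissue_markers <- sort(take(n_tis))
    genotype_markers <- lapply(seq_len(ng), function(i) sort(take(m_per_g)))
    names(genotype_markers) <- genotypes
    # per-genotype metabotype signature strength: a shared gradient across
    # tissues, so the two tissue dendrograms carry correlated genotype
    # structure instead of a noise-driven regular simplex
    genotype_effect_mult <- stats::setNames(stats::runif(ng, 0.4, 1.6), genotypes)
    drought <- sort(take(n_dr))
    drought_tissue_specific <- drought[seq_len(length(drought) %/% 2)]
    drought_sign <- stats::setNames(rep_len(c(1, -1), length(drought)), NULL)
    biomass_linked <- sort(take(n_biom))

    structure(list(
      genotypes = genotypes, ln_b = ln_b, k = k,
      shoot_meanlog = shoot_meanlog,
      drought_shoot_mult = shoot_mult, drought_root_mult = root_mult,
      background = background, tissue_markers = tissue_markers,
      genotype_markers = genotype_markers,
      genotype_effect_mult = genotype_effect_mult,
      drought_responsive = drought,
      drought_tissue_specific = drought_tissue_specific,
      drought_sign = drought_sign,
      biomass_linked = biomass_linked,
      n_features = nf,
      zeros = NULL, missing = NULL, outliers = NULL,
      cleaning = NULL
    ), class = "ground_truth")
  })
}

#' Simulate per-plant shoot and root dry weights
#'
#' Shoot dry weight is log-normal around each accession's mean (accession
#' means span 0.15-0.45 g); root dry weight follows the allometric power law
#' on the log scale, `ln y = ln b_i + k_i ln x + Normal(0, noise_sd)`.
#' Drought multipliers act on the cell means (constant within an accession x
#' regime cell), so per-accession log-log slopes are preserved.
#'
#' @param design output of [generate_design()].
#' @param truth output of [make_ground_truth()].
#' @param noise_sd residual SD of ln(root); >= 0 (0 gives exact allometry,
#'   used by recovery oracles).
#' @param shoot_sdlog plant-to-plant SD of ln(shoot) within a cell.
#' @param seed integer seed.
#' @return data.frame `plant_id, genotype, regime, shoot_dw_g, root_dw_g`.
#' @export
simulate_biomass <- function(design, truth, noise_sd = 0.15, shoot_sdlog = 0.2,
                             seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(is.finite(truth$ln_b)) || !all(is.finite(truth$k)))
    stop("allometry coefficients must be finite")
  plants <- unique(design[c("plant_id", "genotype", "regime", "replicate")])
  plants <- plants[order(plants$plant_id), ]
  rownames(plants) <- NULL
  # the stressed regime is the second level in design order
  stressed <- unique(design$regime)[2]
  local_seed(substream(seed, "biomass"), {
    g <- plants$genotype
    is_dr <- plants$regime == stressed
    ln_shoot <- truth$shoot_meanlog[g] +
      ifelse(is_dr, log(truth$drought_shoot_mult[g]), 0) +
      stats::rnorm(nrow(plants), 0, shoot_sdlog)
    ln_root <- truth$ln_b[g] + truth$k[g] * ln_shoot +
      ifelse(is_dr, log(truth$drought_root_mult[g]), 0) +
      stats::rnorm(nrow(plants), 0, noise_sd)
    out <- data.frame(plant_id = plants$plant_id, genotype = g,
                      regime = plants$regime,
                      shoot_dw_g = exp(ln_shoot), root_dw_g = exp(ln_root))
    stopifnot(all(out$shoot_dw_g > 0), all(out$root_dw_g > 0))
    out
  })
}

# Columns of an n x F matrix (n <= a few) that strictly violate the type-7
# Q +/- 3*IQR fences. Returns a logical vector over columns.
.fence_violation <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(FALSE, ncol(m)))
  srt <- matrix(m[order(col(m), m)], nrow = n)
  counts <- rep(n, ncol(m))
  q1 <- colwise_type7(srt, counts, 0.25)
  q3 <- colwise_type7(srt, counts, 0.75)
  iqr <- q3 - q1
  up <- q3 + 3 * iqr
  lo <- q1 - 3 * iqr
  colSums(m > rep(up, each = n)) + colSums(m < rep(lo, each = n)) > 0
}

#' Simulate a metabolite feature table with blanks and recorded artifacts
#'
#' Log-normal abundances with additive log2-scale planted effects: tissue
#' markers shift in the belowground tissue, each genotype's marker set shifts
#' in that genotype's samples, drought-responsive features shift (alternating
#' sign) under the stressed regime (half of them only in the belowground
#' tissue), and biomass-linked features track each plant's within-cell biomass
#' residual. Zeros, missing values and extreme outliers (x 2^7) are injected
#' at the stated rates with coordinates recorded in the returned ground truth.
#'
#' Clean replicate spread is bounded by construction: within-cell noise is
#' resampled (then deviation-shrunk) until no clean cell violates the 3 x IQR
#' type-7 fences, so that every fence violation in the output is an injected
#' artifact. See the methods vignette for the rationale.
#'
#' @param design output of [generate_design()].
#' @param truth output of [make_ground_truth()].
#' @param effect_sizes list with log2-scale shifts `tissue`, `genotype`,
#'   `regime`, `biomass`. The tissue effect must exceed both the genotype and
#'   the regime effect (the dominant-variance axis of the emulated study).
#' @param missing_rate,outlier_rate,zero_rate artifact rates in `[0, 1)`.
#' @param noise_sd log2-scale replicate noise SD.
#' @param n_blanks number of blank samples.
#' @param seed integer seed.
#' @param biomass optional output of [simulate_biomass()]; required for the
#'   biomass-linked features to carry signal.
#' @return list with `table` (a [feature_table()]), `blanks` (matrix) and
#'   `truth` (ground truth updated with artifact coordinates).
#' @export
simulate_feature_table <- function(design, truth,
                                   effect_sizes = list(tissue = 4, genotype = 3.5,
                                                       regime = 0.4, biomass = 0.8),
                                   missing_rate = 0.01, outlier_rate = 0.002,
                                   zero_rate = 0.005, noise_sd = 0.4,
                                   n_blanks = 6L, seed = 1L, biomass = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  rates <- c(missing_rate, outlier_rate, zero_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must lie in [0, 1)")
  es <- effect_sizes
  if (!(es$tissue > es$genotype && es$tissue > es$regime))
    stop("configuration error: the tissue effect must exceed the genotype ",
         "and regime effects at the stated defaults")
  S <- nrow(design)
  local_seed(substream(seed, "features"), {
    n_feat <- truth$n_features
    feat_ids <- sprintf(paste0("F%0", max(4L, nchar(n_feat)), "d"), seq_len(n_feat))
    mu <- stats::rnorm(n_feat, 14, 1.5)

    Z <- matrix(mu, S, n_feat, byrow = TRUE)
    below <- design$tissue == unique(design$tissue)[2]
    regimes <- unique(design$regime)
    stressed <- design$regime == regimes[2]

    Z[below, truth$tissue_markers] <- Z[below, truth$tissue_markers] + es$tissue
    gmult <- truth$genotype_effect_mult %||%
      stats::setNames(rep(1, length(truth$genotype_markers)),
                      names(truth$genotype_markers))
    for (g in names(truth$genotype_markers)) {
      rows <- design$genotype == g
      cols <- truth$genotype_markers[[g]]
      Z[rows, cols] <- Z[rows, cols] + es$genotype * gmult[[g]]
    }
    dr_all <- setdiff(truth$drought_responsive, truth$drought_tissue_specific)
    sgn <- truth$drought_sign
    names(sgn) <- as.character(truth$drought_responsive)
    if (length(dr_all))
      Z[stressed, dr_all] <- sweep(Z[stressed, dr_all, drop = FALSE], 2,
                                   es$regime * sgn[as.character(dr_all)], "+")
    ts <- truth$drought_tissue_specific
    if (length(ts))
      Z[stressed & below, ts] <- sweep(Z[stressed & below, ts, drop = FALSE], 2,
                                       es$regime * sgn[as.character(ts)], "+")
    if (!is.null(biomass) && length(truth$biomass_linked)) {
      total <- log(biomass$shoot_dw_g + biomass$root_dw_g)
      cell <- interaction(biomass$genotype, biomass$regime, drop = TRUE)
      z <- stats::ave(total, cell, FUN = function(v) {
        s <- stats::sd(v)
        if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
      })
      z <- pmin(pmax(z, -2), 2)
      names(z) <- biomass$plant_id
      Z[, truth$biomass_linked] <- Z[, truth$biomass_linked] +
        es$biomass * z[design$plant_id]
    }

    E <- matrix(stats::rnorm(S * n_feat, 0, noise_sd), S, n_feat)
    raw <- 2^(Z + E)

    # Enforce the clean-table contract: no 3*IQR fence violation in any cell.
    cells <- interaction(design$genotype, design$regime, design$tissue, drop = TRUE)
    n_resampled <- 0L; n_shrunk <- 0L
    for (cl in levels(cells)) {
      rows <- which(cells == cl)
      if (length(rows) < 5L) next # n <= 4 can never violate (see vignette)
      bad <- which(.fence_violation(raw[rows, , drop = FALSE]))
      round <- 0L
      while (length(bad) && round < 20L) {
        n_resampled <- n_resampled + length(bad)
        E[rows, bad] <- stats::rnorm(length(rows) * length(bad), 0, noise_sd)
        raw[rows, bad] <- 2^(Z[rows, bad] + E[rows, bad])
        bad <- bad[.fence_violation(raw[rows, bad, drop = FALSE])]
        round <- round + 1L
      }
      while (length(bad)) { # shrink deviations toward the cell mean
        n_shrunk <- n_shrunk + length(bad)
        lv <- log2(raw[rows, bad, drop = FALSE])
        ctr <- matrix(colMeans(lv), length(rows), length(bad), byrow = TRUE)
        raw[rows, bad] <- 2^((lv - ctr) * 0.7 + ctr)
        bad <- bad[.fence_violation(raw[rows, bad, drop = FALSE])]
      }
    }

    # Inject artifacts at disjoint random coordinates. Outliers are kept off
    # the background features: an injected spike would inflate a background
    # feature's sample mean and mask it from the blank-ratio rule.
    n_cells <- S * n_feat
    n_zero <- round(zero_rate * n_cells)
    n_miss <- round(missing_rate * n_cells)
    n_out <- round(outlier_rate * n_cells)
    picked <- sample.int(n_cells, n_zero + n_miss + n_out)
    zero_idx <- picked[seq_len(n_zero)]
    miss_idx <- picked[n_zero + seq_len(n_miss)]
    out_idx <- picked[n_zero + n_miss + seq_len(n_out)]
    on_bg <- ((out_idx - 1L) %/% S + 1L) %in% truth$background
    if (any(on_bg)) {
      pool <- setdiff(seq_len(n_cells)[-picked],
                      as.vector(outer(seq_len(S), (truth$background - 1L) * S, "+")))
      out_idx[on_bg] <- sample(pool, sum(on_bg))
    }
    coord_df <- function(idx) data.frame(
      sample_id = design$sample_id[(idx - 1L) %% S + 1L],
      feature = feat_ids[(idx - 1L) %/% S + 1L])
    raw[zero_idx] <- 0
    raw[miss_idx] <- NA_real_
    raw[out_idx] <- raw[out_idx] * 2^7

    blanks <- matrix(0, n_blanks, n_feat,
                     dimnames = list(paste0("blank", seq_len(n_blanks)), feat_ids))
    blanks[, truth$background] <-
      0.8 * 2^(matrix(mu[truth$background], n_blanks,
                      length(truth$background), byrow = TRUE) +
                 stats::rnorm(n_blanks * length(truth$background), 0, 0.1))

    colnames(raw) <- feat_ids
    truth$zeros <- coord_df(zero_idx)
    truth$missing <- coord_df(miss_idx)
    truth$outliers <- coord_df(out_idx)
    truth$cleaning <- list(resampled = n_resampled, shrunk = n_shrunk)
    truth$feature_ids <- feat_ids
    list(table = feature_table(raw, design), blanks = blanks, truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [generate_design()], [make_ground_truth()],
#' [simulate_biomass()] and [simulate_feature_table()] on one seed stream.
#'
#' @param spec a [design_spec()].
#' @param ... passed to [simulate_feature_table()].
#' @param noise_sd_biomass residual SD of ln(root).
#' @return list with `spec`, `design`, `truth`, `biomass`, `table`, `blanks`.
#' @export
synth_study <- function(spec, ..., noise_sd_biomass = 0.15) {
  design <- generate_design(spec)
  truth <- make_ground_truth(spec)
  biomass <- simulate_biomass(design, truth, noise_sd = noise_sd_biomass,
                              seed = spec$seed)
  sim <- simulate_feature_table(design, truth, seed = spec$seed,
                                biomass = biomass, ...)
  list(spec = spec, design = design, truth = sim$truth, biomass = biomass,
       table = sim$table, blanks = sim$blanks)
}

#' Serialize ground truth to JSON
#'
#' @param truth a `ground_truth`.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
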