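# Hierarchical shoot-root allometry.
#
# Model, per accession i and plant j:
#   ln y_ij = ln b_i + k_i * ln x_ij + eps_ij,   eps ~ Normal(0, sigma^2)
#   ln b_i ~ Normal(mu_b, tau_b^2),  k_i ~ Normal(mu_k, tau_k^2)
# with weakly informative priors mu_k ~ N(0, 1), mu_b ~ N(-1, 2), and
# half-Normal(1) priors on tau_b, tau_k and sigma. Accession coefficients are
# partially pooled: accessions with few plants shrink toward the population
# line, which is the point of fitting hierarchically rather than per-accession
# OLS. Sampling is Gibbs (conjugate normal blocks) with slice updates for the
# three scale parameters; convergence is gated on split R-hat <= 1.05.

#' Fit the Bayesian hierarchical allometric model
#'
#' @param biomass data.frame in the biomass dialect (`plant_id, genotype,
#'   regime, shoot_dw_g, root_dw_g`); fit one regime at a time.
#' @param priors list with elements `mu_k = c(mean, sd)`, `mu_lnb = c(mean,
#'   sd)`, and half-normal scales `tau_k`, `tau_lnb`, `sigma`.
#' @param chains number of chains (default 4).
#' @param iter post-warmup draws per chain (default 1000).
#' @param warmup warmup iterations per chain (default 1000).
#' @param seed integer seed.
#' @param rhat_max convergence gate on split R-hat (default 1.05).
#' @return an `allometry_fit`: per-accession posterior summaries (`summary`),
#'   posterior draws (`draws`), population-line estimates (`population`),
#'   per-parameter split R-hat (`rhat`) and a `converged` flag. A
#'   non-converged fit is returned flagged, never silently.
#' @export
fit_allometry_bhm <- function(biomass,
                              priors = list(mu_k = c(0, 1), mu_lnb = c(-1, 2),
                                            tau_k = 1, tau_lnb = 1, sigma = 1),
                              chains = 4L, iter = 1000L, warmup = 1000L,
                              seed = 1L, rhat_max = 1.05) {
  if (any(biomass$shoot_dw_g <= 0) || any(biomass$root_dw_g <= 0))
    stop("biomass weights must be strictly positive")
  gcount <- table(biomass$genotype)
  if (any(gcount < 2L))
    stop("every accession needs at least 2 plants (",
         paste(names(gcount)[gcount < 2], collapse = ", "), ")")
  x <- log(biomass$shoot_dw_g)
  y <- log(biomass$root_dw_g)
  gf <- factor(biomass$genotype)
  G <- nlevels(gf)
  gi <- as.integer(gf)
  n_g <- tabulate(gi, G)
  Sx <- vapply(seq_len(G), function(g) sum(x[gi == g]), 0)
  Sxx <- vapply(seq_len(G), function(g) sum(x[gi == g]^2), 0)
  Sy <- vapply(seq_len(G), function(g) sum(y[gi == g]), 0)
  Sxy <- vapply(seq_len(G), function(g) sum(x[gi == g] * y[gi == g]), 0)

  ols <- t(vapply(seq_len(G), function(g) {
    xs <- x[gi == g]; ys <- y[gi == g]
    if (stats::var(xs) == 0) return(c(NA_real_, NA_real_))
    fit <- stats::lm.fit(cbind(1, xs), ys)
    fit$coefficients
  }, c(0, 0)))

  half_norm <- function(s, scale) -0.5 * (s / scale)^2 # log density up to const
  keep <- array(NA_real_, dim = c(iter, chains, 2L * G + 5L))

  for (ch in seq_len(chains)) {
    local_seed(substream(seed, paste0("bhm_chain", ch)), {
      a <- ifelse(is.na(ols[, 1]), mean(y) - mean(x), ols[, 1]) +
        stats::rnorm(G, 0, 0.1)
      k <- ifelse(is.na(ols[, 2]), 0.4, ols[, 2]) + stats::rnorm(G, 0, 0.1)
      mu_a <- mean(a); mu_k <- mean(k)
      sd0 <- function(v) { s <- stats::sd(v); if (is.na(s)) 0.3 else s }
      tau_a <- max(sd0(a), 0.1); tau_k <- max(sd0(k), 0.1)
      sigma <- max(stats::sd(y - a[gi] - k[gi] * x), 0.05)
      for (it in seq_len(warmup + iter)) {
        # (ln b_i, k_i) | rest : bivariate normal per accession
        inv_s2 <- 1 / sigma^2
        for (g in seq_len(G)) {
          p11 <- n_g[g] * inv_s2 + 1 / tau_a^2
          p12 <- Sx[g] * inv_s2
          p22 <- Sxx[g] * inv_s2 + 1 / tau_k^2
          b1 <- Sy[g] * inv_s2 + mu_a / tau_a^2
          b2 <- Sxy[g] * inv_s2 + mu_k / tau_k^2
          # draw via the Cholesky factor of the 2x2 PRECISION (numerically
          # stable even when sigma is tiny and shoot sizes are correlated)
          l11 <- sqrt(p11)
          l21 <- p12 / l11
          l22 <- sqrt(max(p22 - l21^2, 1e-12))
          v1 <- b1 / l11
          v2 <- (b2 - l21 * v1) / l22
          m2 <- v2 / l22
          m1 <- (v1 - l21 * m2) / l11
          z <- stats::rnorm(2L)
          u2 <- z[2] / l22
          u1 <- (z[1] - l21 * u2) / l11
          a[g] <- m1 + u1
          k[g] <- m2 + u2
        }
        # population means | rest
        prec <- G / tau_a^2 + 1 / priors$mu_lnb[2]^2
        mu_a <- stats::rnorm(1L, (sum(a) / tau_a^2 +
                                    priors$mu_lnb[1] / priors$mu_lnb[2]^2) / prec,
                             sqrt(1 / prec))
        prec <- G / tau_k^2 + 1 / priors$mu_k[2]^2
        mu_k <- stats::rnorm(1L, (sum(k) / tau_k^2 +
                                    priors$mu_k[1] / priors$mu_k[2]^2) / prec,
                             sqrt(1 / prec))
        # scale parameters | rest : slice sample on the log scale, two sweeps
        # for better mixing; floors keep degenerate (noiseless / single
        # accession) posteriors numerically sane
        res <- y - a[gi] - k[gi] * x
        sse <- sum(res^2)
        n <- length(y)
        for (sweep in 1:2) {
          sigma <- max(1e-4, exp(slice_sample1(log(sigma), function(ls) {
            s <- exp(ls)
            -n * ls - sse / (2 * s^2) + half_norm(s, priors$sigma) + ls
          }, w = 0.5)))
          ssa <- sum((a - mu_a)^2)
          tau_a <- max(1e-4, exp(slice_sample1(log(tau_a), function(ls) {
            s <- exp(ls)
            -G * ls - ssa / (2 * s^2) + half_norm(s, priors$tau_lnb) + ls
          }, w = 0.5)))
          ssk <- sum((k - mu_k)^2)
          tau_k <- max(1e-4, exp(slice_sample1(log(tau_k), function(ls) {
            s <- exp(ls)
            -G * ls - ssk / (2 * s^2) + half_norm(s, priors$tau_k) + ls
          }, w = 0.5)))
        }
        # interweaving (ASIS) rescan: re-draw each scale and population mean
        # with the standardized deviations held fixed. This breaks the
        # funnel-shaped coupling between tau and the group effects that makes
        # a purely centered Gibbs scan mix slowly.
        inv_s2 <- 1 / sigma^2
        at <- (a - mu_a) / tau_a
        r_a <- y - k[gi] * x - mu_a
        wa <- at[gi]
        tau_a <- max(1e-4, exp(slice_sample1(log(tau_a), function(ls) {
          s <- exp(ls)
          -sum((r_a - s * wa)^2) * inv_s2 / 2 + half_norm(s, priors$tau_lnb) + ls
        }, w = 0.5)))
        prec <- n * inv_s2 + 1 / priors$mu_lnb[2]^2
        mu_a <- stats::rnorm(1L, (sum(y - k[gi] * x - tau_a * wa) * inv_s2 +
                                    priors$mu_lnb[1] / priors$mu_lnb[2]^2) / prec,
                             sqrt(1 / prec))
        a <- mu_a + tau_a * at
        kt <- (k - mu_k) / tau_k
        r_k <- y - a[gi] - mu_k * x
        wk <- kt[gi] * x
        tau_k <- max(1e-4, exp(slice_sample1(log(tau_k), function(ls) {
          s <- exp(ls)
          -sum((r_k - s * wk)^2) * inv_s2 / 2 + half_norm(s, priors$tau_k) + ls
        }, w = 0.5)))
        prec <- sum(x^2) * inv_s2 + 1 / priors$mu_k[2]^2
        mu_k <- stats::rnorm(1L, (sum(x * (y - a[gi] - tau_k * wk)) * inv_s2 +
                                    priors$mu_k[1] / priors$mu_k[2]^2) / prec,
                             sqrt(1 / prec))
        k <- mu_k + tau_k * kt
        if (it > warmup)
          keep[it - warmup, ch, ] <- c(a, k, mu_a, mu_k, tau_a, tau_k, sigma)
      }
    })
  }

  gl <- levels(gf)
  par_names <- c(paste0("lnb[", gl, "]"), paste0("k[", gl, "]"),
                 "mu_lnb", "mu_k", "tau_lnb", "tau_k", "sigma")
  dimnames(keep)[[3]] <- par_names
  rhat <- vapply(seq_along(par_names),
                 function(j) split_rhat(keep[, , j, drop = TRUE]), 0)
  names(rhat) <- par_names
  converged <- all(rhat <= rhat_max, na.rm = TRUE)
  if (!converged)
    warning("allometry fit flagged: split R-hat > ", rhat_max,
            " for ", sum(rhat > rhat_max, na.rm = TRUE), " parameter(s)")

  flat <- matrix(keep, nrow = iter * chains,
                 dimnames = list(NULL, par_names))
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  smry <- data.frame(genotype = gl, n_plants = n_g,
                     lnb_mean = colMeans(flat[, seq_len(G), drop = FALSE]),
                     k_mean = colMeans(flat[, G + seq_len(G), drop = FALSE]))
  ci_b <- t(apply(flat[, seq_len(G), drop = FALSE], 2, qs))
  ci_k <- t(apply(flat[, G + seq_len(G), drop = FALSE], 2, qs))
  smry$lnb_lo <- ci_b[, 1]; smry$lnb_hi <- ci_b[, 2]
  smry$k_lo <- ci_k[, 1]; smry$k_hi <- ci_k[, 2]
  smry$k_ols <- ols[, 2]
  rownames(smry) <- NULL

  structure(list(summary = smry, draws = flat,
                 population = c(mu_lnb = mean(flat[, "mu_lnb"]),
                                mu_k = mean(flat[, "mu_k"]),
                                tau_lnb = mean(flat[, "tau_lnb"]),
                                tau_k = mean(flat[, "tau_k"]),
                                sigma = mean(flat[, "sigma"])),
                 rhat = rhat, converged = converged,
                 chains = chains, iter = iter, warmup = warmup, seed = seed),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("<allometry_fit> ", nrow(x$summary), " accessions | ",
      x$chains, " chains x ", x$iter, " draws | converged: ",
      x$converged, "\n", sep = "")
  cat(sprintf("  population: ln b = %.3f, k = %.3f, sigma = %.3f\n",
              x$population["mu_lnb"], x$population["mu_k"],
              x$population["sigma"]))
  cat(sprintf("  accession k range: [%.3f, %.3f]\n",
              min(x$summary$k_mean), max(x$summary$k_mean)))
  invisible(x)
}

#' Root mass fraction per accession
#'
#' RMF = root / (root + shoot) per plant, averaged per accession.
#'
#' @param biomass data.frame in the biomass dialect.
#' @return data.frame `genotype, rmf` (per-plant values attached as the
#'   `"per_plant"` attribute).
#' @export
compute_rmf <- function(biomass) {
  stopifnot(all(biomass$shoot_dw_g > 0), all(biomass$root_dw_g > 0))
  per_plant <- biomass$root_dw_g / (biomass$shoot_dw_g + biomass$root_dw_g)
  agg <- stats::aggregate(list(rmf = per_plant),
                          by = list(genotype = biomass$genotype), FUN = mean)
  attr(agg, "per_plant") <- stats::setNames(per_plant, biomass$plant_id)
  agg
}

#' Per-accession drought effect on biomass with unequal variances
#'
#' For each accession and trait (shoot, root, total dry weight), a two-group
#' comparison of drought vs control allowing a different variance in every
#' accession x regime cell (Welch form of the heteroscedastic linear model):
#' estimate, standard error, Welch-Satterthwaite p-value, and percent change
#' `100 * (mean_drought - mean_control) / mean_control`.
#'
#' @param biomass data.frame in the biomass dialect with both regimes.
#' @param control,drought regime labels.
#' @return data.frame, one row per accession x trait; accessions with a cell
#'   of fewer than 2 plants are flagged (`tested = FALSE`) and skipped.
#' @export
test_drought_biomass <- function(biomass, control = "control",
                                 drought = "drought") {
  traits <- list(shoot = biomass$shoot_dw_g, root = biomass$root_dw_g,
                 total = biomass$shoot_dw_g + biomass$root_dw_g)
  out <- list()
  for (g in unique(biomass$genotype)) {
    for (tr in names(traits)) {
      v <- traits[[tr]]
      vc <- v[biomass$genotype == g & biomass$regime == control]
      vd <- v[biomass$genotype == g & biomass$regime == drought]
      if (length(vc) < 2L || length(vd) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          genotype = g, trait = tr, estimate = NA_real_, se = NA_real_,
          df = NA_real_, p = NA_real_, pct_change = NA_real_, tested = FALSE)
        next
      }
      mc <- mean(vc); md <- mean(vd)
      s2c <- stats::var(vc) / length(vc)
      s2d <- stats::var(vd) / length(vd)
      se <- sqrt(s2c + s2d)
      est <- md - mc
      if (se == 0) {
        p <- if (est == 0) 1 else 0
        df <- length(vc) + length(vd) - 2
      } else {
        df <- (s2c + s2d)^2 / (s2c^2 / (length(vc) - 1) + s2d^2 / (length(vd) - 1))
        p <- 2 * stats::pt(-abs(est / se), df)
      }
      out[[length(out) + 1L]] <- data.frame(
        genotype = g, trait = tr, estimate = est, se = se, df = df, p = p,
        pct_change = 100 * est / mc, tested = TRUE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
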