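---
title: "Models and methods behind metabotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metabotyper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metabotyper` analyses designed untargeted-metabolomics studies over a
genotype × tissue × water-regime factorial and links the metabolite profiles
(metabotypes) both backwards to genotype and forwards to biomass phenotypes.
This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, the numerical
choices that had to be fixed, and what the synthetic-data generator does and
does not establish. It states no empirical result that the test suite does
not itself compute.

## 1. Feature-table filtering

The canonical filter order is **background → zeros-to-NA → presence →
outliers**, in `filter_pipeline()`.

* **Background removal** (`remove_background`): a feature is background when
  its mean abundance across experimental blanks is at least
  `ratio_threshold` (default 0.5) times its mean abundance across samples.
  The source procedure states *that* blank-derived background is removed but
  not the rule; the ratio-of-means rule with a logged threshold is our
  parameterisation.
* **Zeros to missing** (`zeros_to_missing`): exact zeros in deconvoluted
  feature tables are non-detections, not measurements of zero; they become
  `NA`. Idempotent by construction.
* **Presence filter** (`presence_filter`): a feature is removed only when
  *every* genotype × regime × tissue cell holds fewer than `min_present`
  (default 3) observed values. The alternative reading ("any cell below 3
  removes the feature") would delete nearly the whole table at realistic
  missingness and is not implemented.
* **Outlier nulling** (`flag_outliers`): per feature and cell, type-7
  quartiles over the observed values; strict violations of
  `Q3 + 3·IQR` / `Q1 − 3·IQR` become `NA`. The quartile convention matters:
  fences move by tens of percent between conventions at n = 5, so it is
  fixed (type 7, R's default: linear interpolation between order statistics)
  and logged.

**A small-sample fact with large consequences.** Under type-7 quartiles with
multiplier 3, a cell with n ≤ 4 observed values can never flag its own
extremum: for n = 4 the upper fence is `max + 3·(x₍₃₎ − Q1) ≥ max`, and the
cases n ≤ 3 are even weaker. Only complete five-replicate cells can flag.
Two consequences are deliberate in this package: (i) recall of injected
outliers requires most affected cells to be complete, so the generator's
default missing/zero rates are low; and (ii) the canonical pipeline is
exactly idempotent — any cell changed by flagging drops to n ≤ 4 and can
flag nothing more, background and presence decisions are unchanged by
flagging (a nulled cell goes 5 → 4 ≥ 3), and blank means never change. The
test suite asserts the fixed point exactly.

The outlier rule is applied to **raw** abundances, before the log2
transform: the filtering procedure precedes the statistical analysis in the
source pipeline, and fences on the raw scale are what the stated formulas
describe.

## 2. Shoot–root allometry

The allometric power law `y = b·xᵏ` is fitted on the log scale,

    ln y_ij = ln b_i + k_i · ln x_ij + ε_ij,   ε ~ Normal(0, σ²)

with accession-level coefficients partially pooled through
`ln b_i ~ N(μ_b, τ_b²)` and `k_i ~ N(μ_k, τ_k²)`. A single regression would
ignore accession differences; separate per-accession OLS would ignore that
all accessions are one species. The hierarchical fit interpolates: an
accession with two plants and a wild exact-fit OLS slope is pulled strongly
toward the population line (tested), while well-observed accessions keep
their own slopes.

**Priors** (the source description names no priors; these are weakly
informative around the plausible allometry regime, and configurable):
`μ_k ~ N(0, 1)`, `μ_b ~ N(−1, 2)`, and half-Normal(1) on `τ_b`, `τ_k`, `σ`.
`ln b_i` and `k_i` are modelled as independent hierarchical normals — the
simplest structure consistent with the stated model; a modelled correlation
is left out.

**Sampler.** Blocked Gibbs: the per-accession pair `(ln b_i, k_i)` is
conjugate bivariate normal (drawn through the Cholesky factor of the 2×2
*precision*, which stays stable when σ → 0); population means are conjugate;
the three scales use log-scale slice sampling. A purely centred scan mixes
slowly in `τ_k` (the usual funnel: weak per-accession slope information
couples `k_i` tightly to `τ_k`), so every iteration ends with an
interweaved (ASIS) rescan that re-draws each scale and population mean with
the standardised deviations held fixed. This drops split R-hat on `τ_k`
from ≈ 1.15 to ≈ 1.02 at the study design size. Defaults: 4 chains × 1000
post-warmup draws after 1000 warmup; convergence gate split R-hat ≤ 1.05,
violations flagged (never silently returned). Scales are floored at 1e-4 so
degenerate noiseless inputs stay finite.

Control and drought are fitted as separate models, mirroring the separate
presentation of the two regimes. `compute_rmf` is plain arithmetic
(`y/(x+y)` per plant, accession means); `test_drought_biomass` is the
heteroscedastic ("different variance per accession") two-group comparison in
Welch form with Satterthwaite degrees of freedom, per accession and trait,
with percent change `100·(m_d − m_c)/m_c`.

## 3. Multivariate structure

**PERMANOVA** (`permanova`). The distance matrix is Gower-centred
(`G = C·(−d²/2)·C`) and partitioned by **sequential (Type-I)** sums of
squares in formula order — the model formula is written as an ordered sum,
and the design is balanced, so order effects are negligible. `SS_term =
tr(P·G)` for the difference `P` of successive hat matrices; pseudo-F is the
usual MS ratio; p-values come from free row permutations with the add-one
convention `(1 + #{F* ≥ F}) / (1 + n_perm)` (study default 10,000
permutations; the pipeline default is 999 for routine runs and is a
parameter). Two numerical points: permutations that happen to reproduce the
observed grouping recompute F in a different summation order, so the
comparison uses a relative 1e-8 tolerance — without it the permutation p is
biased low by exactly the tie mass, and the exhaustive-enumeration check
fails; and a term with zero degrees of freedom is dropped with a warning.
Free (unrestricted) permutation is used for all terms including
interactions; restricted/strata permutation is a documented non-feature.

**Imputation + PCA.** `impute_pca` initialises missing cells at feature
means and alternates a rank-`n_components` truncated SVD reconstruction with
refilling of the missing cells until the RMS change of imputed cells falls
below `tol`. Observed cells are never altered; non-convergence returns a
flag, not an error. The reconstruction rank before PCA is not stated by the
source analysis; the default is 5 and it is a parameter. `pca` is a plain
column-centred (optionally unit-variance, the study's choice) SVD; zero
variance columns are dropped with a warning when scaling.

**Clustering.** `hcluster_ward_squared` implements the Ward variant in
which the dissimilarities are *squared before cluster updating*: the
Lance–Williams Ward recurrence applied to d². On squared Euclidean input
each merge height equals twice the Ward objective increase (the within-
cluster SS growth), which is what the brute-force oracle in the acceptance
suite recomputes; the merge sequence also coincides with `hclust(d²,
"ward.D")`, which is cross-checked. Ties merge the lowest-index pair, so
results are platform-deterministic. `cut_tree` applies the first `n − k`
merges, which resolves any tie at the cut height by merge order and makes
cuts nested by construction.

**Baker's gamma** (`bakers_gamma`). For every leaf pair, each tree records
the number of clusters present when the pair first co-clusters; γ is the
**Goodman–Kruskal** rank correlation between the two pair-depth vectors,
with tied pairs ignored — Baker's original index. Spearman on the same
vectors was considered and rejected: the depth vectors of any dendrogram
carry large forced tie blocks (only one pair can merge first), and under
average-rank ties Spearman's attainable minimum on four leaves is −0.483,
so the index would not span its nominal [−1, 1] range; Goodman–Kruskal
attains exactly −1 on fully reversed 4-leaf trees and +1 on identical
trees. The permutation test permutes the leaf labels of one tree (default
1000 times) and uses the add-one convention. γ is computed from the joint
contingency table of the two depth vectors in O(r·c) per evaluation, so a
1000-permutation test on genotype-level trees costs milliseconds.

## 4. Differential metabolites

Per tissue and genotype, each metabolite gets a one-way two-group ANOVA of
drought vs control on log2 abundances — numerically the squared pooled-t
(`F = t²`, verified against `t.test` in the suite). A combination is
testable only when both groups hold ≥ 2 values (the ANOVA presence filter
`anova_presence_filter` reports, per tissue, the metabolites testable for no
genotype — the analogue of the source's per-tissue removal counts). The
**Holm family is all testable metabolites within one genotype × tissue**:
significant-metabolite counts are reported per genotype, which implies
per-genotype families; the choice is documented and configurable by passing
your own families through `holm_adjust`. Log-fold change is the difference
of group means on the log2 scale. Heatmap rows are z-standardised with the
n−1 SD convention; zero-SD rows become zeros and are flagged.

## 5. Coherence

Plants (with their two tissue profiles concatenated, `plant_profiles`) are
clustered per regime into as many clusters as genotypes. A genotype is
**coherent** iff its replicates occupy a single cluster *and* that cluster
contains no other genotype's plants. The purity requirement implements
"unique enough to distinguish from the other genotypes"; the unanimity-only
variant is available via `require_purity = FALSE`. The coherence fraction is
invariant to cluster relabelling and rises monotonically (in median) with
the generator's genotype-signature strength — both tested.

## 6. Biomass prediction

`fit_biomass_predictor` is a bagged CART regression forest (compiled;
variance-reduction splits, mtry random feature subsets, bootstrap per tree)
over metabolite features plus genotype one-hot indicators, so the model must
find metabolites informative *beyond* genotype identity. Tuning is 5-fold
CV over mtry ∈ {√p, p/3, p/10} with 500 trees by default; the reported RMSE
(grams) is the mean of per-fold RMSEs for the selected mtry, matching the
"average of the CV prediction statistics" convention. Importance is
**permutation importance on out-of-fold data** (mean MSE increase when one
column is shuffled in the held-out fold): model-agnostic, fold-consistent,
and unaffected by the impurity biases of split-count importances; the
alternative was not specified by the source and this choice is logged.
`ablation_rmse_delta` refits without a named feature group under identical
folds and seed and reports the percent RMSE increase. Ridge/LASSO/neural
net/SVM comparisons that the source tried and discarded are intentionally
absent.

## 7. The synthetic world

`synth_study` generates: 30 genotypes × 2 tissues × 2 regimes × 5
replicates and 2,897 features by default; log-normal abundances (log2
baseline ~ N(14, 1.5), replicate noise SD 0.4 log2 units ≈ 30% CV);
planted, disjoint feature sets — 2% background (present in blanks at 80% of
sample level, making the 0.5 ratio rule decidable), 10% tissue markers
(+4 log2 in belowground), 12% genotype markers (≈ 12 per genotype, shifted
+3.5 × a per-genotype strength multiplier uniform on [0.4, 1.6]), 3.5%
drought-responsive (±0.4, half belowground-only), 1% biomass-linked
(tracking the plant's within-cell biomass residual, clamped at ±2 SD);
artifacts injected at recorded coordinates (1% missing, 0.5% zeros, 0.2%
outliers at ×2⁷). Biomass: accession shoot means log-uniform over
0.15–0.45 g, k_i uniform on [0.16, 0.67], ln b_i uniform on [−2.1, −1.4]
(placing root weights in the 0.05–0.25 g band), residual SD 0.15 on
ln(root); drought multipliers per accession, root ×[0.76, 2.23] (−24% to
+123%) and shoot ×[0.7, 1.3], applied to cell means so log-log slopes are
preserved. All values are either ranges the emulated study reports or
realism choices fixed once and documented here.

Three generator choices deserve emphasis:

* **Bounded clean noise.** Any unimodal replicate noise leaves ~10–15% of
  five-value cells with natural 3·IQR fence violations (a small-sample
  quartile effect, measured for normal, uniform and log-normal noise). The
  generator's contract is that the clean table contains *no* fence
  violation — heavy tails enter only through injected artifacts — so
  within-cell noise is resampled (bounded rounds, then deviation shrinkage)
  until every cell is fence-clean. This is what makes injected-outlier
  recall/false-positive rates well-defined and the filter pipeline
  idempotent. Outliers are additionally kept off background features, whose
  inflated sample means would otherwise mask them from the blank-ratio rule.
* **Per-genotype signature strengths.** Equal-magnitude disjoint marker
  sets would place all genotypes on a regular simplex — every pair
  equidistant — so dendrogram topology would be pure noise and the two
  tissue trees uncorrelated. The strength multiplier creates a genotype
  similarity gradient shared across tissues, giving the correlated
  aboveground/belowground dendrograms (high Baker's γ, significant
  permutation p) that the emulated study design exhibits.
* **Effect ordering.** Defaults satisfy pseudo-F(tissue) ≫
  pseudo-F(genotype) > pseudo-F(regime) *and* SS(tissue) ≫ SS(genotype) >
  SS(regime), the generator's stated contract. This is a property of the
  synthetic world, not a reproduction of any real-data F values.

**What a green test does not establish.** The generator starts at the
deconvoluted feature-table level: no chromatograms, retention times, m/z
values, instrument drift, batch structure, or feature-intensity dependence
of missingness (missingness here is uniform, not abundance-dependent as in
real MS data). Effects are additive on the log scale with homoscedastic
noise. Consequently the suite establishes correctness of the statistical
machinery on a faithful *design*, not performance on real instrument data;
the emulated study's own headline numbers (specific pseudo-F values, γ,
coherence percentages, RMSE in grams) come from undeposited raw tables and
are out of reach by construction.

## 8. Pipeline and reproducibility

`run_pipeline` executes simulate → validate → filter → allometry →
multivariate → differential → coherence → predict from one serializable
config. Every stochastic stage draws from a named substream of the base
seed (`substream(seed, name)`), so stages can be toggled without changing
the draws of the others, and the run report (versions, seeds, filter counts,
convergence flags — no timestamps) is byte-identical across reruns of the
same config. Acceptance-suite simulation sizes are scaled down where a
criterion permits (noted inline in the tests); rates, effect sizes,
tolerances and fence rules are never scaled.

## 9. Known limitations

* Free permutation for interaction terms (no strata); adequate for balanced
  designs, approximate otherwise.
* The Holm family choice (per genotype × tissue) changes significant-count
  magnitudes relative to a global family; both are defensible, one is
  implemented as default.
* The forest uses a fixed small mtry grid and no depth tuning; it is a
  mechanism for importance/ablation statistics, not a leaderboard model.
* The Gibbs sampler assumes the stated independent-normal hierarchy; a
  correlated (ln b, k) prior is not implemented.
* PERMANOVA cost grows as n²·n_perm; the study-scale 600-sample,
  10,000-permutation run takes minutes, so routine pipeline runs default to
  999 permutations (a config parameter, not a cap).
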