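Package: metabotyper
Title: Genotype-Metabotype-Phenotype Mapping for Designed Metabolomics Studies
Version: 1.0.0
Authors@R: person("PREMIS", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping plant genotypes to metabolite profiles
    (metabotypes) and metabotypes to external biomass phenotypes in factorial
    genotype x tissue x water-regime designs. Provides a ground-truthed synthetic
    study generator; the four-step metabolomics feature-table filter (blank-based
    background removal, zero-to-missing conversion, cell-factor presence filtering,
    and 3xIQR outlier nulling); Bayesian hierarchical shoot-root allometry with a
    Gibbs sampler; full-factorial PERMANOVA with permutation p-values; iterative
    low-rank missing-value imputation and PCA; Ward clustering on squared
    dissimilarities with Baker's gamma dendrogram comparison; per-genotype
    drought-response ANOVA with Holm correction; genotype-metabotype coherence
    statistics; and cross-validated random-forest biomass prediction with
    permutation importance and feature-group ablation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
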