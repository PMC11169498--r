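Package: firemsom
Title: Multi-Species Royle-Nichols Abundance Models for Post-Fire Mammal Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing terrestrial mammal responses to wildfire with
    camera-trap and environmental DNA data. Builds 5-day occasion detection
    histories from camera-trap records (including 500-m station merging and
    data augmentation), extracts land-cover and burned-area covariates in
    circular buffers from categorical grids, and fits a hierarchical Bayesian
    multi-species Royle-Nichols abundance model with data augmentation by
    Metropolis-within-Gibbs MCMC (Rcpp core). Derives site-level species
    richness and aggregated relative abundance, classifies covariate effects by
    credible-interval support, runs the frequentist post-hoc layer (normality
    gate, Welch t, Wilcoxon rank-sum, linear regressions), performs
    assemblage-composition set algebra, and applies eDNA metabarcoding curation
    rules. A synthetic-community generator emulating the study design makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
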