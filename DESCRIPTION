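Package: phenopred
Title: Phenomic and Genomic Prediction for Hybrid Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing genomic
    prediction (SNP markers) with phenomic prediction (seed near-infrared
    reflectance spectra) in structured test-hybrid breeding populations.
    Provides a synthetic-data generator for multi-environment partially
    replicated field trials and plot-level NIR spectra, REML-based
    adjustment of traits and spectra to entry means (BLUEs) with Cullis
    heritability, Savitzky-Golay spectral preprocessing, VanRaden and
    NIRS relationship matrices, Gaussian kernels, five prediction models
    (G/NIRS-BLUP, Bayesian LASSO, RKHS kernel averaging, random forest,
    support vector regression), random and familywise cross-validation,
    and selection-accuracy statistics based on the Czekanowski
    coefficient.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    signal,
    ranger,
    kernlab,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
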