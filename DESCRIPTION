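Package: neuroraman
Title: Raman Spectral Classification and Unmixing for Brain Injury Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A chemometrics pipeline for discriminating traumatic brain
    injury from healthy brain tissue in fibre-probe Raman spectra.
    Provides a synthetic-spectrum generator (pseudo-Voigt band libraries,
    fluorescence baselines, cosmic-ray spikes, class-dependent lipid
    composition), preprocessing (cross-accumulation cosmic-ray removal,
    asymmetric-reweighted spline baseline correction, resampling and
    normalization), a hexagonal self-organizing map classifier with
    per-neuron class-label vectors and a SOM discriminant index (SOMDI),
    and non-negative least-squares unmixing of brain-lipid reference
    components with group-level ANOVA, tied together by a seeded,
    manifest-producing pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    pracma,
    yaml,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
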