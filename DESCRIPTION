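Package: milsd
Title: Multiple-Illumination Learned Spectral Decoloring for Optoacoustic Oximetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative optoacoustic (photoacoustic) oximetry by learned
    spectral decoloring with multiple illumination positions (MI-LSD).
    Provides chromophore spectral models for a copper/nickel sulfate
    blood-mimicking phantom system and for whole-blood hemoglobin, a
    randomized digital tube-phantom sampler with deterministic phantom
    layouts, a desk-scale 2D optical forward engine (voxel Monte Carlo and a
    finite-difference diffusion surrogate) producing multi-illumination
    multispectral absorbed-energy stacks, L1-normalized feature extraction
    with mirrored-illumination augmentation, random forest and feedforward
    neural network saturation regressors, a nonnegative linear spectral
    unmixing baseline, and error-distribution reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    ranger,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'RcppExports.R'
    'decoloring.R'
    'estimators.R'
    'evaluation.R'
    'phantom.R'
    'fluence.R'
    'io.R'
    'milsd-package.R'
    'nn.R'
    'pipeline.R'
    'spectral.R'
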