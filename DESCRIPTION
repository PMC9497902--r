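Package: hyperpH
Title: Hyperspectral Imaging Chemometrics for Pixel-Wise pH Prediction in
    Processed Meats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end chemometrics workflow for visible/near-infrared
    hyperspectral imaging of sausages: dark/white reflectance calibration,
    threshold segmentation with equal-area region splitting, spectral
    pretreatment chains (Savitzky-Golay derivatives, multiplicative scatter
    correction, standard normal variate, area normalization), partial least
    squares regression fitted by NIPALS with cross-validated latent-variable
    selection, feature-wavelength selection from the regression-coefficient
    profile, and pixel-wise pH prediction maps. Also implements the five-factor
    central composite design and quadratic response-surface analysis (Type III
    ANOVA with lack-of-fit decomposition) used to study casing-modification
    factors, and a synthetic phantom generator so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    signal,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Regression, Preprocessing, ExperimentalDesign, Spectroscopy
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'chemometrics.R'
    'featureSelection.R'
    'hypercube.R'
    'hyperpH-package.R'
    'io.R'
    'mapping.R'
    'pipeline.R'
    'preprocessing.R'
    'presets.R'
    'rsm.R'
    'segmentation.R'
    'spectraSet.R'
    'synthetic.R'
    'utils.R'
    'wavelengthGrid.R'
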