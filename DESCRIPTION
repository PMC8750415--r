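Package: specAuth
Title: Chemometric Authentication of Milk Powder from Miniature NIR Sensors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking spectroscopy-based food-authentication
    workflows on miniature near-infrared (NIR) sensors, using skimmed milk
    powder adulteration as the model system. Provides a seeded synthetic
    spectra generator emulating a multi-device, multi-adulterant sample design
    with realistic device artifacts; standard spectral preprocessing (SNV,
    Savitzky-Golay derivatives, Pareto scaling); one-class SIMCA classification
    with score/orthogonal distances and F-based critical limits; OPLS
    regression with sample-wise (Venetian blinds) cross-validation; elliptical
    joint confidence region (EJCR) bias testing; pseudo-univariate limits of
    detection and quantification; and an end-to-end study pipeline producing a
    per-device scorecard.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Regression, Cheminformatics, QualityControl
Collate: 
    'specAuth-package.R'
    'AllClasses.R'
    'componentLibrary.R'
    'composition.R'
    'devices.R'
    'generate.R'
    'io.R'
    'merit.R'
    'opls.R'
    'pipeline.R'
    'preprocessing.R'
    'simca.R'
    'utils.R'
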