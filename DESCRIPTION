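Package: blinkid
Title: Single-Molecule Peptide Identification from Fluorophore Blinking Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying single peptide molecules from the
    fluorescence-intermittency ("blinking") pattern of an attached
    spontaneously blinking fluorophore. Provides an exact stochastic
    simulator of class-dependent ON/OFF photoswitching with conformational
    modulation and photobleaching, a synthetic TIRF movie renderer with
    ground truth, spot detection and trace extraction, hand-crafted
    blinking-feature baselines (PCA, Fourier, classical classifiers), and a
    one-dimensional convolutional / gated-recurrent-unit deep classifier
    with Monte Carlo dropout uncertainty filtering, trained directly on
    normalized intensity traces. Includes dataset splitting with
    replicate-aware grouping, confusion-matrix evaluation, plain-text
    interchange formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    tiff,
    zoo,
    ranger,
    e1071,
    glmnet,
    class
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
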