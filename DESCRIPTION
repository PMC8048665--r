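Package: qsmphantom
Title: In Silico Head Phantom Simulation and Evaluation for Quantitative
    Susceptibility Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds realistic digital head phantoms for quantitative
    susceptibility mapping (QSM): composes a ground-truth magnetic
    susceptibility volume from tissue labels and relaxometry maps with
    partial-volume and reliability weighting, simulates multi-echo spoiled
    gradient-echo complex data by k-space dipole convolution (with
    background fields, polynomial shimming, transceiver phase, noise,
    Fourier-crop downsampling and a white-matter microstructure frequency
    term), provides a reference phase-processing chain (region-growing
    unwrapping, optimum-weight echo combination, Laplacian boundary-value
    background removal), baseline dipole inversions (thresholded k-space
    division and closed-form L2), and the QSM-challenge evaluation metric
    suite. A seeded synthetic head generator makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils-image.R'
    'forward-field.R'
    'inversion.R'
    'tissue-table.R'
    'metrics.R'
    'phase-pipeline.R'
    'signal-sim.R'
    'phantom-model.R'
    'synthetic-head.R'
    'io-pipeline.R'
    'qsmphantom-package.R'
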