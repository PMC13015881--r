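Package: paintmsi
Title: MALDI Mass Spectrometry Imaging Workflow for Multilayer Paint Stratigraphy
Version: 0.1.0
Authors@R:
    person("paintmsi", "developers", email = "paintmsi@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for decoding the layer structure of paint
    cross sections from MALDI mass spectrometry imaging (MSI) data. Provides
    imzML input/output, spectral preprocessing (prominence-based peak picking,
    ppm binning, TIC normalization), annotation of pigments and binders against
    a packaged colourant database with exact-mass and isotopic-pattern scoring,
    Kendrick mass defect and referenced-KMD analysis for metal-containing
    pigments, brightfield-to-MSI registration and colour-threshold mask
    extraction, and a sparse-regression composition classifier (per-class LASSO
    with bootstrap averaging and Gaussian-mixture posterior gating into an
    Uncertain class). A synthetic-data module generates multilayer paint
    replicas with ground truth so the entire pipeline can be exercised and
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
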