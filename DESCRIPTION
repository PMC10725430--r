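Package: gliaquant
Title: Quantitative Analysis of Astrocyte Structure, Metabolism and Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a complete quantitative pipeline for single-cell studies
    of cortical astrocytes and neurons: cubic-spline baseline correction of Raman
    microspectra and cytochrome redox ratio metrics; segmentation of dye-filled
    astrocytes from two-photon z-stacks (coherence-enhancing diffusion,
    per-plane hysteresis thresholding, size filtering) with domain-area and
    leaflet volume-fraction estimation; 3D Sholl analysis and branch metrics on
    SWC tracings; patch-clamp feature extraction (input resistance, IV curves,
    action-potential train features, spontaneous IPSC detection); immunostain
    coverage and intensity-ratio metrics; and two-group nonparametric
    comparison with box-whisker summaries. A synthetic-data module generates
    every input modality with known ground truth for validation and power
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
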