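Package: ktrpipe
Title: Single-Cell Kinase Translocation Reporter Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative single-cell imaging analysis for kinase
    translocation reporter (KTR) experiments: flat-field illumination
    correction, nuclear segmentation of fixed (histogram thresholding with
    watershed splitting) and live (Laplacian-of-Gaussian blob detection)
    cells, lineage tracking with global assignment, gap bridging and
    mitosis detection, cytoplasm-to-nucleus ratio extraction over an
    annular cytoplasm proxy, cell-cycle phase calling from degron
    reporters, drug-persister classification from CDK2 activity traces,
    four-parameter logistic dose-response (IC50) fitting, Bliss
    independence synergy scoring, caliper tumor-volume computation, and
    tumor-section morphometry (margin-distance fields and periphery/core
    immune-cell densities). Includes a seeded synthetic-data generator
    producing movies, traces, dose matrices and tumor sections with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    clue,
    minpack.lm,
    mclust,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
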