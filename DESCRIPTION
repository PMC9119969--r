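Package: rpequant
Title: Quantitative Assay Pipelines for Retinal Pigment Epithelium Scarring Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable quantification pipelines for the in vitro assays used in
    retinal scarring (proliferative vitreoretinopathy) studies of micelle-forming
    polymer treatments: phase-contrast cell confluence and growth curves via
    local-entropy texture segmentation, two-channel fluorescence nuclei counting
    with Ki67 positivity calling and NRF2 nuclear mean-fluorescence intensity,
    scratch-wound recovery quantification, critical micelle concentration
    estimation by two-line breakpoint regression on dye-solubilisation curves,
    quadratic standard-curve fitting and inversion for micelle-shedding
    quantitation, LDH cytotoxicity normalisation, comparative-CT qPCR fold
    changes, differential-expression gene-set overlap summaries, and the
    accompanying statistical reporting (one-way ANOVA with Tukey HSD, unpaired
    t-tests, Pearson correlation). A seeded synthetic-data module generates
    every pipeline input with machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
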