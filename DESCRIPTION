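Package: nucleoscreen
Title: High-Content Screen Analysis of mtDNA Nucleoids in Depletion-Syndrome Fibroblasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for high-content imaging screens of
    mitochondrial DNA (mtDNA) content in fibroblasts, as used to evaluate
    deoxynucleoside supplementation in mtDNA depletion syndrome models.
    Provides a synthetic field-image generator with known ground truth
    (nuclei, mtDNA nucleoid puncta, membrane-potential reticulum), size-based
    segmentation and per-cell quantification (nucleoid counts and summed
    puncta area, nuclear and mitochondrial integrated densities, reticulum
    length, Rho-0 and ploidy classification), baseline-normalised screen
    statistics with normality-gated tests and linear mixed models, qPCR
    relative copy-number analysis of depletion-recovery time courses, and
    stable-isotope label-dilution inference of limiting nucleoside pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
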