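Package: isquant
Title: Quantification of Endoplasmic-Reticulum Remodeling at the B-Cell
    Immune Synapse from 3-D Confocal Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-slice Z-scan fluorescence profiles, synapse-plane (first 10%
    of Z-slices) enrichment, bead polarity index, masked-ROI Pearson
    colocalization, MTOC-proximal mean density, line scans, and ER
    area/volume morphometry for single-cell multi-channel confocal stacks of
    B cells forming immune synapses. Includes a synthetic 3-D stack generator
    with measured ground truth for end-to-end validation, batch pipeline
    orchestration, and between-condition statistics (one-way ANOVA with Tukey
    HSD, Student's t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
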