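Package: peakreg
Title: Regression of ChIP-Seq Peak Scores on Binding-Motif Features
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies transcription factor binding motifs that explain
    ChIP-Seq peak enrichment scores. Peaks are uniformized to fixed-width
    sequences, scored against candidate position-specific scoring matrices
    (best sliding log-odds match relative to the maximum achievable score,
    shifted and Euclidean-normalized per peak), and the log peak scores are
    regressed on the resulting feature matrix with L1-regularized linear
    regression (with ordinary least squares, ridge, partial least squares
    and principal component regression available for comparison).
    Downstream utilities cluster binary motif-presence vectors to propose
    composite motifs, and test motif-mapped base positions for depletion of
    known SNPs with a hypergeometric test. A synthetic-data generator with
    planted motifs and known regression weights supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
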