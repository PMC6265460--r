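Package: scquantal
Title: Quantal Analysis of Single-Cell qPCR Gene Induction
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell qPCR (Fluidigm Biomark style)
    studies of all-or-none ("quantal") gene induction, built around pulsatile
    GnRH stimulation of pituitary gonadotrope cells. Provides Ct-matrix import
    and the 41 - Ct expression transform, housekeeping-based well QC, binary
    expression calling and per-gene modality assessment, per-condition
    activation probabilities with binomial errors, induced-level invariance
    testing, exact per-dose estimates and Hill-constrained binomial
    dose-response fits with gene sensitivity ranking, a cell-cycle phase
    scorer, log-CPM sample correlation reports, and a ground-truth synthetic
    data generator for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
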