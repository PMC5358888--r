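Package: rbcforecast
Title: Biomarker-Driven Forecasting of Metabolite Concentrations in
    Stored Red Blood Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative prediction of metabolite concentration time
    courses in stored red blood cells from a small panel of extracellular
    biomarkers.  Implements finite-impulse-response (Output-Error with
    nf = 0) model identification by least squares, per-replicate ensemble
    training with median-consensus prediction, symmetric mean absolute
    percentage error (SMAPE) scoring, exhaustive biomarker-subset
    selection by leave-one-replicate-out cross-validation, a naive
    random-walk Monte-Carlo significance benchmark, and a synthetic-data
    generator that emulates a multi-replicate cold-storage metabolomics
    time course so the whole workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
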