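Package: fluxdeconv
Title: Deconvolution of Whole-Organism Extracellular Flux Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bioenergetic profiling of small whole organisms
    (developing zebrafish embryos in particular) from microplate
    extracellular-flux respirometry. Converts raw microchamber level traces
    (O2 tension, pH) to per-cycle oxygen-consumption and extracellular
    acidification rates with a diffusion-aware two-compartment model,
    converts acidification to proton-production rates via measured buffer
    capacity, cross-calibrates against Clark-electrode rates, and
    deconvolutes basal respiration into non-mitochondrial, ATP-turnover,
    proton-leak and maximal-uncoupled components using an
    oligomycin/FCCP/azide injection protocol. Includes a ground-truthed
    synthetic assay generator for end-to-end validation, and the statistical
    comparisons used in this field (one-way ANOVA with Student-Newman-Keuls
    post hoc, one-sample t tests, titration dose selection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
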