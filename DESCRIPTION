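Package: csmux
Title: Design and Simulation of CRISPRi Channel-Selector Circuits for
    Multiplexed Cell-Cell Communication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and modeling genetic channel-selector
    devices that time-share a single quorum-sensing (AHL) communication
    channel between multiple transcriptional conversations. Includes
    exhaustive synthesis of minimal NOT/NOR gate networks for
    multiplexer/demultiplexer truth tables, Hill transfer-function models
    and fitting for CRISPRi gates and small-molecule sensors, steady-state
    and dynamical co-culture simulation over an AHL wire with dilution
    protocols, an orthogonal sgRNA:promoter library design pipeline with
    genomic off-target screening and graph-based diversity selection,
    synthetic flow-cytometry data generators, and the evaluation metrics
    used to score model predictions (RMSE in MEFL decades, density gating,
    FL3 classification, logarithmic binning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    deSolve,
    minpack.lm,
    Biostrings,
    BiocGenerics,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
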