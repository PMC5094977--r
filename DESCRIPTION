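Package: cellavatar
Title: Virtual Cell-Line Avatars for Signaling-Network Drug Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds desk-scale virtual cell-line avatars by overlaying genomic
    aberrations (gain/loss-of-function mutations and copy-number changes) on a
    logic-based ODE model of a signaling network, then simulates a staged
    control/disease/drug/micro-environment protocol to predict phenotype
    readouts. Includes multi-target drug pharmacology with a calibrated
    reference-dose convention, dose-response sweeps, IC-level search,
    combination grids, Loewe isobologram construction with combination-index
    synergy calls, cytokine micro-environment conditions, phenotype indices
    (proliferation, survival, apoptosis, viability) with weight calibration
    against qualitative trend tables, and curated JAK2-V617F myeloproliferative
    neoplasm fixtures (HEL and SET2 avatars, the JAK2 inhibitor G6 and the
    BCL2 inhibitor ABT737).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
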