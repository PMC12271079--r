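Package: lineageCycle
Title: Stochastic Lineage-Level Cell-Cycle Simulation and Duration
    Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates mammalian cell-cycle progression across cell
    lineages with a growth-factor-driven CycB/Cdh1/Cdc20 oscillator whose
    transcription rates fluctuate as Ornstein-Uhlenbeck colored noise, are
    inherited at division and randomly reset at mitosis.  Provides
    calibration of the deterministic limit cycle to target cycle and G1
    durations, extraction of sister, mother-daughter and cousin
    duration pairs from simulated lineage forests, Pearson correlation and
    cousin-mother-inequality statistics with bootstrap significance, and
    sweep drivers over noise correlation time, noise strength, cycle and
    phase durations and growth-factor level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
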