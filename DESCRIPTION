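Package: cyclescope
Title: Cell-Cycle-Resolved Transcription Rate Inference from Single-Cell
    Reporter Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study cell-cycle-dependent transcription in budding
    yeast from fluorescent-reporter data. Includes a stochastic simulator of
    single-cell lineages (two-phase volume growth, mRNA birth-death with
    time-varying transcription rate, fluorophore maturation, division
    partitioning, measurement noise), smoothing-spline inversion of the
    transcription-translation ODE pair to recover per-cell mRNA levels and
    instantaneous transcription rates, in-silico cell-cycle synchronization
    and progression-rescaled population profiles with bootstrap errors,
    ON/OFF event detection with step-test response-delay estimation and
    co-activation statistics, cell-cycle-phase-dependent Poisson-mixture
    models for snapshot mRNA count distributions, and quantification of
    mRNA spots in synthetic single-molecule FISH images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
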