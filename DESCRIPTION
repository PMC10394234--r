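Package: mmnsource
Title: Mismatch Negativity Source Analysis for Psychosis-Risk EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for auditory mismatch negativity
    (MMN) in psychosis-risk cohorts. Provides a constrained pseudo-random
    oddball stimulus sequence generator, an analytic multi-shell spherical-head
    EEG forward model with three regional sources (bilateral auditory cortex
    and frontal cortex), a synthetic raw-EEG cohort generator with
    group-specific frontal MMN deficits, ERP preprocessing (average reference,
    1-20 Hz zero-phase filtering, epoching, baseline correction, amplitude and
    ocular artifact rejection), sensor-level MMN difference-wave peak measures,
    fixed three-source waveform estimation by least squares, and the cohort
    statistics layer (one-way ANOVA with Bonferroni post-hoc tests,
    correlations, and unadjusted/adjusted logistic transition models).
    BrainVision Core triplets are read and written for raw data exchange.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, jsonlite, yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), signal, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
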