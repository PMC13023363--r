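Package: taperstates
Title: Seizure-State Decomposition and Anti-Seizure Medication Taper Analysis for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how anti-seizure medication (ASM) withdrawal shapes
    seizure dynamics recorded on intracranial EEG. Seizure activity is
    decomposed into recurring spatio-frequency "states" by non-negative matrix
    factorization of region-by-band power, dosing schedules are converted to a
    normalized continuous ASM level via one-compartment pharmacokinetics,
    taper-emergent states (states confined to the tapered-medication condition)
    are detected, and dose effects on seizure frequency and duration are
    quantified with linear mixed-effects models, circadian covariates, and
    rank-based effect sizes. A synthetic-cohort generator with known ground
    truth supports parameter-recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
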