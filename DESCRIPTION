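Package: pbbm
Title: Mechanistic Physiologically-Based Biopharmaceutics Modelling of Oral
    Drug Absorption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanistic physiologically-based biopharmaceutics
    modelling (PBBM) of orally administered ionizable drugs, built around
    fasted-state ibuprofen as the worked system. Provides pH-dependent
    solubility of monoprotic acids, a six-state gastrointestinal
    dissolution-and-transit ODE model with migrating-motor-complex
    phase-III gastric emptying, simultaneous fitting of the model to
    luminal and plasma concentrations, non-compartmental analysis and
    Wagner-Nelson deconvolution, mammillary intravenous pharmacokinetic
    fitting with AIC model selection, a nine-compartment
    absorption-and-transit simulator with static or time-varying fluid
    volume and pH schedules, spectral detection of phase-III motility from
    manometry traces, and a virtual-cohort generator so that every stage
    of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    glmnet,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
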