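Package: cogadapt
Title: Adaptive Cognitive-Training Engine with Tri-Persona Coordination,
    Safety Monitoring and Feasibility-Trial Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Engine for computerized adaptive cognitive training in older
    adults: a two-parameter logistic (2PL) success-probability model with
    difficulty updates targeting an 85% success rate, maximum-likelihood
    ability tracking with exponential smoothing, and a weighted
    cognitive-load metric over response-time deviation, error rate and
    attention variance. Around the engine it implements a deterministic
    three-persona (coach, teacher, companion) coordination state machine,
    clinical safety-monitoring rules (discontinuation criteria, response
    filtering, fidelity sampling, escalation), a six-week protocol
    scheduler with adherence metrics and feasibility criteria, scoring for
    the study instruments (SUS, PANAS, BPNS, UEQ-S, MDPQ-16, CARS), and a
    simulated-participant cohort generator so the full feasibility
    protocol can be dry-run on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
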