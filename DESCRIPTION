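Package: oiload
Title: Bone-Implant Interface Loads for Transhumeral Osseointegrated Prostheses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates forces and moments at the bone-implant interface of
    transhumeral percutaneous osseointegrated endoprostheses during advanced
    activities of daily living. Builds subject-scaled rigid-body models of the
    upper limb, performs virtual amputation at fractional humeral lengths,
    substitutes mass-distribution models of four commercial prosthesis classes,
    and computes intersegmental loads by Newton-Euler inverse dynamics,
    resolving them into bending moment, torsional moment and axial pullout
    force. Includes a seeded synthetic kinematics generator standing in for a
    motion-capture corpus, peak-load statistics with log-scale mixed-effects
    comparisons and signed-rank threshold tests, published time-zero failure
    envelopes for exceedance flagging, and a single-trial sensitivity analysis
    over segment mass and centre-of-mass perturbations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
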