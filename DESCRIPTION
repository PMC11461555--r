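Package: ckdscreen
Title: Optimal Chronic Kidney Disease Screening Schedules for Diabetics via a
    Finite-Horizon POMDP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design and evaluate chronic kidney disease (CKD)
    screening schedules for adults with diagnosed diabetes. A natural-history
    microsimulation of eGFR decline, proteinuria onset and mortality
    parameterizes a finite-horizon partially observable Markov decision
    process (10 health states, screen/wait actions, quarterly epochs from age
    30 to 85), which is solved exactly by backward induction over the
    reachable belief set. The resulting policy is evaluated against annual
    status-quo screening on net monetary benefit, cost, QALY and averted-case
    outcomes, translated into age-binned screening-frequency guidelines, and
    stress-tested by a one-way and simultaneous sensitivity-analysis engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
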