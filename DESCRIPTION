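Package: oxmiscea
Title: Decision-Tree Cost-Effectiveness Model for Structured Suicide Risk
    Assessment in Severe Mental Illness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a one-year decision-analytic cost-effectiveness
    model comparing structured suicide risk assessment with the OxMIS
    prediction tool against unstructured clinical assessment in people
    with severe mental illness. Provides the validated base-case
    parameter set, a decision-tree engine computing expected per-patient
    costs and quality-adjusted life years, likelihood-ratio updating for
    a sequential (clinical-then-OxMIS) scenario, incremental
    cost-effectiveness metrics (ICER, net monetary benefit, dominance
    classification), deterministic (tornado) and probabilistic (Monte
    Carlo) sensitivity analysis with cost-effectiveness acceptability
    curves, and a patient-level microsimulation that cross-validates the
    analytic tree expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
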