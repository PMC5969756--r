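Package: nhsmcea
Title: Non-Homogeneous Multi-State Cost-Effectiveness Analysis for ICU
    Catheter-Related Bloodstream Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a discrete-time, non-homogeneous eight-state multi-state
    model to longitudinal individual-patient ICU trajectory data and turns
    it into a full cost-effectiveness analysis of skin-antiseptic
    strategies for the prevention of catheter-related bloodstream
    infections (CRBSI). Provides daily transition-probability estimation
    from panel data, state-occupancy (prevalence) curves, expected total
    length of stay and expected visits per state, first-passage CRBSI risk
    per 1000 patients, a per-state Euro-2016 cost engine, pairwise
    incremental cost-effectiveness ratios (ICER) with dominance
    classification, patient-level nonparametric bootstrap with Efron's
    bias-corrected and accelerated (BCa) intervals, and a calibrated
    synthetic-cohort generator emulating a four-arm ICU trial.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
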