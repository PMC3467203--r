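Package: apixcea
Title: Markov Cohort Cost-Effectiveness Model of Apixaban Versus Warfarin
    in Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A state-transition (Markov) cohort model comparing apixaban
    5 mg twice daily with adjusted-dose warfarin for stroke prevention in
    non-valvular atrial fibrillation, from the US Medicare perspective in
    2012 dollars.  Provides the deterministic cohort trace over composite
    health states (ischemic stroke, intracranial and extracranial
    hemorrhage, myocardial infarction, aspirin switching, death), lifetime
    discounted cost/QALY/life-year outcomes and incremental
    cost-effectiveness ratios, one-way and two-way sensitivity analyses
    with bisection threshold search, probabilistic sensitivity analysis
    with triangular parameter distributions, and a patient-level
    microsimulation that serves as a brute-force validation oracle for the
    cohort engine and as a generator of synthetic event histories.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
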