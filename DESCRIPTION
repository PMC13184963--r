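Package: strokecea
Title: Decision-Analytic Modelling of Acute Ischemic Stroke Care Improvement Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-stage decision-analytic model for acute ischemic stroke (AIS)
    care: a 90-day decision tree over standard medical care, intravenous
    thrombolysis (IVT) and endovascular treatment (EVT), followed by a lifetime
    Markov cohort model over modified Rankin Scale (mRS) bands with a one-year
    recurrent-stroke tunnel state, background life-table mortality and
    discounting. Implements six stroke-care improvement targets (treatment
    rates, onset-to-treatment times, primary and secondary prevention),
    incremental cost-effectiveness analysis with dominance classification,
    population-level scaling, one-way deterministic sensitivity analysis with
    tornado ordering, and probabilistic sensitivity analysis with constrained
    beta sampling. Ships a synthetic country-input generator, seven
    preconfigured European country fixtures, a microsimulation validation
    oracle and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
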