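Package: pandemicCEA
Title: Cost-Effectiveness Modeling of Indirect Pandemic Health Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A condition-agnostic cost-effectiveness framework for the
    indirect health effects of a pandemic. Estimates excess prevalence,
    quality-adjusted life years (QALYs) lost, and societal costs attributable
    to pandemic-driven increases in adult health conditions; evaluates
    mitigation interventions (coverage, efficacy, unit cost) with a
    time-phased cost-accrual schedule, dominance/ICER classification,
    probabilistic sensitivity analysis, and one-way deterministic sensitivity
    analysis. Ships six calibrated example scenarios (depression, intimate
    partner violence, homelessness, excessive alcohol use, opioid use
    disorder, stroke mortality) reconstructed from published summary tables,
    plus a random scenario generator for property testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
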