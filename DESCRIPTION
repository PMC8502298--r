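Package: hfcea
Title: Markov Cohort Cost-Effectiveness Modelling for Heart Failure Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model for the cost-effectiveness of
    add-on dapagliflozin versus standard care in heart failure with reduced
    ejection fraction (HFrEF). Provides probability/rate conversions over
    arbitrary horizons, a four-state monthly-cycle cohort engine with a
    microsimulation oracle, incremental cost-effectiveness measures (ICER, net
    monetary benefit, willingness-to-pay decisions), deterministic (tornado)
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, a declarative scenario/battery runner, a claims-based
    cost-estimation procedure (stable, event-month, state-month and death-month
    costs), and a synthetic longitudinal claims generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
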