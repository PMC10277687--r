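Package: hfcem
Title: Cohort State-Transition Cost-Effectiveness Modelling for Heart Failure Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lifetime Markov cohort state-transition model for cost-utility
    analysis of add-on therapy versus standard of care in heart failure with
    reduced ejection fraction. Health states are KCCQ-CSS quartiles (or NYHA
    classes) plus death; the clinical engine combines period-specific
    transition matrices, proportional-hazards Weibull/exponential survival
    equations for all-cause and cardiovascular death with a general-population
    life-table floor on non-cardiovascular death, a Poisson recurrent
    heart-failure-hospitalisation rate model, exponential treatment
    discontinuation, and constant adverse-event incidences. Monthly cycles
    with half-cycle correction accrue discounted costs and QALYs; outputs
    include ICERs, net monetary benefit, tornado-style deterministic
    sensitivity analysis, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and scenario runs. A synthetic
    parameter generator and a patient-level micro-simulation oracle make every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
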