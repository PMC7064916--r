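Package: cibpcrm
Title: Convex Infinite Bounds Penalization for Phase I Dose-Escalation Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the convex infinite bounds penalization (CIBP)
    allocation criterion for Bayesian model-based phase I dose-escalation
    trials, embedded in the one-parameter power-model continual reassessment
    method (CRM), together with comparator designs (CRM, modified CRM,
    escalation with overdose control and its alpha-schedule variants,
    Bayesian logistic regression model) and a simulation harness for
    operating characteristics (selection probabilities, proportion of
    correct selections, accuracy index, dose-limiting toxicity summaries).
    Posteriors are computed by deterministic grid quadrature for exact
    reproducibility; heavy-tailed allocation scores are evaluated on the
    log scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
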