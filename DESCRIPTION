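Package: qaopr
Title: Quantitative Adverse Outcome Pathway Modeling for Repeated Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies an adverse outcome pathway (AOP) for chronic toxicity
    under repeated exposure. Provides a virtual-data simulator with
    donor-specific onset of chronic-phase responses, lognormal resampling with
    cross-response correlation and Gaussian-Bayesian updating across exposure
    repetitions, per-exposure static Gaussian Bayesian networks with
    logic-sampling activation probabilities and volume-under-surface summaries,
    a non-stationary first-order dynamic Bayesian network for transition
    probabilities of the adverse outcome, and lasso-based data-driven pruning
    of the pathway structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    lme4,
    MASS,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
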