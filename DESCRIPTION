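Package: safetybbn
Title: Data-Driven Bayesian Belief Networks for Organizational Patient-Safety Factors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating hospital-level organizational factor
    scores (staff-survey aggregates on a 0-10 scale) to the proportion of
    staff reporting patient-safety errors, through discrete Bayesian belief
    networks. Provides a Gaussian-copula synthetic survey generator calibrated
    to published marginal moments and Spearman rank correlations,
    uniform-width discretization, three structure learners (constraint-based
    PC with G-squared conditional-independence tests, score-based greedy
    thick thinning and hill-climbing Bayesian search under the BDeu score),
    exact inference by variable elimination, k-fold cross-validated
    prediction of the safety-error state, and an evidence-propagation
    scenario engine producing vulnerability- and resilience-based factor
    rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
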