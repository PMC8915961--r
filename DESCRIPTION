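Package: covertsig
Title: Covert and Overt Identity Signaling in Heterogeneous Audiences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying covert versus overt identity signaling under
    mixed audiences. Provides the closed-form expected-payoff model for
    signaling to an audience containing outgroup members (with the
    covert-favorability threshold in outgroup proportion and a Monte-Carlo
    check), a rater-based covert/overt classification of short political
    messages with an interrater Shapley variance decomposition, a
    follower-network heterogeneity pipeline (media-diet scoring, engagement
    labeling, homogeneous/heterogeneous seed classification, tweet filters),
    the behavioral-experiment analysis stack (majority-rule payouts,
    reception-rate estimation, mixed-effects Poisson models, average
    predictive margins and marginal effects, BIC-approximate Bayes factors),
    and synthetic-data generators so the whole pipeline runs and is tested
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
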