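Package: trialrisk
Title: Decision-Theoretic Bayesian Clinical Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of Bayesian clinical trials from a
    decision-theoretic viewpoint. Combines testing, estimation and sampling
    losses into an integrated risk for conjugate normal and binomial outcome
    models; test decisions use cost-reweighted posterior-probability
    thresholds equivalent to Bayes-factor thresholding. Operating
    characteristics (average type I/II error rates, average mean squared
    error, indeterminate-outcome probability, and Phase-III power-loss and
    sample-size-gain monitors) are averaged over a sampling prior, which may
    differ from the analysis prior to probe sensitivity to prior-data
    conflict. Per-observation costs are elicited from goal-sampling targets
    by differentiating operating-characteristic curves, and the optimal
    sample size minimizes the resulting risk. Supports vague, informative,
    robust mixture and empirical-Bayes power analysis priors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
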