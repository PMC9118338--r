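# Normal-outcome simulation scenario: known variance 1, one-sided test of
# theta <= 0 with relevance threshold 0.15. Historical information
# (mean 0.25, 50 observations) enters the informative, robust-mixture and
# EB power analysis priors; the sampling prior matches the informative one.
model:
  family: normal
  sigma2: 1.0
hypotheses:
  theta0: 0.0
  thetaR: 0.15
analysis_priors:
  vague:
    type: normal
    mean: 0.0
    var: 100.0
  informative:
    type: normal
    mean: 0.25
    var: 0.02
  robust_mixture:
    type: mixture
    weights: [0.5, 0.5]
    components:
      - {type: normal, mean: 0.25, var: 0.02}
      - {type: normal, mean: 0.25, var: 100.0}
  eb_power:
    type: power
    a0: empirical_bayes
    baseline: {type: normal, mean: 0.0, var: 100.0}
    historical: {n0: 50, mean: 0.25}
sampling:
  type: normal
  mean: 0.25
  var: 0.02
  grid: {mean_from: -0.3, mean_to: 0.5, points: 9}
costs:
  c0p: 0.05
  c1p: 0.95
  mode: bf_reweighted
phase3:
  target_power: 0.9
  alpha3: 0.025
  zeta: 0.2
elicitation:
  analysis_prior: vague
  n_sate: 160           # pay 160 patients for average type II error <= 0.2
  n_amse: 180           # pay 180 for the estimation monitors
  smooth_sate: false    # normal-family curves are smooth; no smoothing
  smooth_amse: false
numerics:
  theta_nodes: 199
  outcome_nodes: 801
  gh_order: 199
  n_grid: {from: 2, to: 300, by: 2}
  eval_n: 100
  seed: 1
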