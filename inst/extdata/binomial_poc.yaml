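# Single-arm proof-of-concept trial with binomial outcome (objective
# response rate in non-small-cell lung cancer). Significance threshold
# 0.075, relevance threshold 0.175. The RSN analysis prior Beta(0.0811, 1)
# has mean 0.075; the informative prior Beta(11, 29) encodes a historical
# study with 10 responses in 38 patients under a uniform baseline.
model:
  family: binomial
hypotheses:
  theta0: 0.075
  thetaR: 0.175
analysis_priors:
  rsn:
    type: beta
    a: 0.0811
    b: 1.0
  informative:
    type: beta
    a: 11.0
    b: 29.0
  robust_mixture:
    type: mixture
    weights: [0.5, 0.5]
    components:
      - {type: beta, a: 11.0, b: 29.0}
      - {type: beta, a: 1.0, b: 1.0}
  eb_power:
    type: power
    a0: empirical_bayes
    baseline: {type: beta, a: 1.0, b: 1.0}
    historical: {n0: 38, successes: 10, failures: 28}
sampling:
  type: beta
  a: 11.0
  b: 29.0
  grid: {mean_from: 0.1, mean_to: 0.65, points: 12}
costs:
  c0p: 0.05
  c1p: 0.95
  mode: bf_reweighted
phase3:
  target_power: 0.9
  alpha3: 0.025
  zeta: 0.2
elicitation:
  analysis_prior: rsn
  n_sate: 21            # average type I <= 0.15 and type II <= 0.2 beyond here
  n_amse: 74            # estimation monitors acceptable beyond here
  smooth_sate: true     # sawtooth SATE curve: smooth before differentiating
  smooth_amse: false    # AMSE declines smoothly; raw central difference
  elicit_grid: {from: 1, to: 300, by: 1}
numerics:
  theta_nodes: 199
  n_grid: {from: 1, to: 150, by: 1}
  eval_n: 25
  seed: 1
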