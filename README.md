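# trialrisk

Decision-theoretic design and evaluation of Bayesian clinical trials with
conjugate normal or binomial outcomes. The package is aimed at
biostatisticians designing early-phase (in particular proof-of-concept)
trials who want to borrow historical information through an analysis prior
while quantifying — rather than forbidding — the resulting departures from
frequentist error control, and who need a principled sample size when
testing, estimation, and per-patient costs all matter.

## The framework

A trial tests `H0: θ ≤ θ0` against `H1: θ > θ0` and additionally declares
*relevance* when the posterior median exceeds a threshold `θR`. Decisions
are driven by an **analysis prior** π_a (vague, informative, robust
mixture, or empirical-Bayes power prior), while operating characteristics
are averaged over a **sampling prior** π_s describing the plausible true
effects — a point mass recovers frequentist operating characteristics, and
varying π_s probes sensitivity to prior-data conflict.

With test-error costs c0′ (false negative) and c1′ (false positive)
reweighted by the inverse prior hypothesis masses, the Bayes-optimal rule
rejects when the posterior null probability falls below

    γ = c0′·P(θ ≤ θ0) / (c0′·P(θ ≤ θ0) + c1′·(1 − P(θ ≤ θ0)))

which is the same as rejecting when the one-sided Bayes factor drops below
c0′/c1′, and makes the test part of the risk the weighted sum of *average*
error rates, SATE(n) = c1′·ᾱ(n) + c0′·β̄(n). The full integrated risk adds
estimation and sampling losses:

    r(n) = (w / cnSATE)·SATE(n) + ((1−w) / cnAMSE)·AMSE(n) + n

where AMSE is the sampling-prior-averaged MSE of the posterior mean. The
per-observation costs cnSATE and cnAMSE are elicited from goal-sampling
targets as negative curve derivatives, w = nSATE/(nSATE + nAMSE), and the
optimal sample size minimizes r(n) on an integer grid. Curves also carry
Phase-III monitors (indeterminate-outcome probability, extreme power loss,
extreme sample-size gain) to ground the estimation target.

## Worked example

The bundled `binomial_poc` scenario is a single-arm proof-of-concept trial
on objective response rate (θ0 = 0.075, θR = 0.175), analyzed with the
rate-matched RSN prior Beta(0.0811, 1) under a Beta(11, 29) sampling prior
(mean 0.275).

```r
library(trialrisk)
sc <- load_scenario(trialrisk_scenarios("binomial_poc"))
run_scenario(sc, "reproduce")
```

```
<cost_elicitation> n_SATE = 21, n_AMSE = 74
  cn_SATE = 0.0001961, cn_AMSE = 3.377e-05, w = 0.221, cq = 20.47, cn = 0.0008871

Operating characteristics at n_SATE:
  n  avg_type1 avg_type2      sate        amse avg_indeterminate
 21 0.05082827 0.1864869 0.0576112 0.008485225                 0
 avg_extreme_power_loss avg_extreme_n_gain risk
              0.4616502           23.95387   NA

Operating characteristics at n_AMSE:
  n avg_type1  avg_type2      sate        amse avg_indeterminate
 74 0.1317982 0.01144858 0.1257807 0.002562691         0.0956648
 avg_extreme_power_loss avg_extreme_n_gain risk
              0.2683195           13.58549   NA

<design_result> n_opt = 64, risk = 208.657
```

Reading: 21 patients suffice for the testing goal (average type II error
below 0.2; SATE = 0.058), but 74 are needed before the estimation monitors
settle (AMSE = 0.0026, indeterminate probability below 0.1). The slopes of
the two curves at those sample sizes imply per-patient costs of about
2.0e-4 (testing) and 3.4e-5 (estimation); weighting the goals by
w = 21/95 = 0.221 and minimizing the combined risk selects **n = 64** —
well above the 25 patients of a power-only design, because limiting the
chance of an under-powered Phase III trial is costly in estimation error.

The same machinery is exposed piecewise (`averaged_oc()`, `oc_curve()`,
`elicit_costs()`, `integrated_risk()`, `optimal_n()`, `goal_n()`,
`sensitivity_scan()`), and a command-line wrapper lives in
`exec/trialrisk`:

```sh
Rscript exec/trialrisk design --config binomial_poc --out results/
```

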