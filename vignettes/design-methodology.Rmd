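---
title: "Decision-theoretic trial design with trialrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-theoretic trial design with trialrisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialrisk)
```

## The design problem

A single-arm trial tests $H_0: \theta \le \theta_0$ against
$H_1: \theta > \theta_0$ for a treatment effect $\theta$, under a conjugate
outcome model: either $\bar{y} \sim N(\theta, \sigma^2/n)$ with known
$\sigma^2$, or a binomial success count $y \sim Bin(n, \theta)$. Beyond
significance, an early-phase (proof-of-concept) trial also asks whether the
effect is *relevant* — large enough to justify a confirmatory Phase III
study — which we encode as the posterior median exceeding a relevance
threshold $\theta_R \ge \theta_0$: $P^{\pi_a}(\theta \le \theta_R \mid y) <
0.5$. A trial declaring exactly one of significance and relevance is
*indeterminate*.

Two priors play distinct roles throughout:

* the **analysis prior** $\pi_a$ is used to fit the data and drives every
  decision. The package ships four archetypes: a vague prior, an
  informative prior built from historical data, a robust mixture of the
  two, and an empirical-Bayes (EB) power prior that discounts the
  historical likelihood by a weight $a_0 \in [0,1]$ chosen by
  marginal-likelihood maximization;
* the **sampling prior** $\pi_s$ describes which effects are believed to
  actually generate the data. Operating characteristics are averaged over
  it; a point-mass sampling prior recovers ordinary frequentist operating
  characteristics, and scanning a grid of sampling priors probes
  sensitivity to prior-data conflict.

## Loss, risk, and the test decision

A $c_0$–$c_1$ test loss charges $c_0$ for a missed effect and $c_1$ for a
false rejection. Minimizing posterior expected loss rejects when
$P^{\pi_a}(\theta \le \theta_0 \mid y) < \gamma$ with
$\gamma = c_0 / (c_0 + c_1)$. The package's default cost mode inflates user
costs $c_0', c_1'$ by the inverse prior hypothesis masses,
$c_0 = c_0'/P^{\pi}(\theta > \theta_0)$ and
$c_1 = c_1'/P^{\pi}(\theta \le \theta_0)$, giving the threshold
$$\gamma^{\pi_a} = \frac{c_0' P^{\pi_a}(\theta \le \theta_0)}
  {c_0' P^{\pi_a}(\theta \le \theta_0) +
   c_1' \{1 - P^{\pi_a}(\theta \le \theta_0)\}}.$$
This choice makes the rule identical to thresholding the one-sided Bayes
factor at $c_0'/c_1'$ (the package verifies the equivalence exhaustively in
its tests) and turns the integrated risk into the **weighted sum of average
test error rates**
$$\mathrm{SATE}(n) = c_1' \bar\alpha(n) + c_0' \bar\beta(n),$$
where $\bar\alpha$ and $\bar\beta$ average the conditional error rates over
the sampling prior restricted to the null and alternative sides of
$\theta_0$. A `plain` cost mode with the fixed threshold $c_0'/(c_0'+c_1')$
is also available; it reproduces conventional posterior-probability rules
(e.g. "reject when $P(\theta > \theta_0 \mid y) \ge 0.95$" for
$c_0' = 0.05$).

Ties at the threshold keep $H_0$: the Bayes-factor form keeps the null when
$c_0'/c_1' \le BF(y)$, and we read the inequality non-strictly. Likewise a
posterior centered exactly at $\theta_R$ is *not* relevant. For
data-dependent priors (EB power prior, mixtures) both the posterior
probability and the threshold are recomputed per dataset from the resolved
prior, since the prior's mass below $\theta_0$ then varies with the data.

Estimation and sampling losses extend the risk to
$$r(n) = \frac{w}{c_n^{SATE}} \mathrm{SATE}(n)
       + \frac{1-w}{c_n^{AMSE}} \mathrm{AMSE}(n) + n,$$
where $\mathrm{AMSE}(n)$ is the mean squared error of the posterior mean
averaged over the whole sampling prior, and the equivalent raw
parameterization uses $c_q = (1-w) c_n^{SATE} / (w\, c_n^{AMSE})$ and
$c_n = c_n^{SATE}/w$. The optimal $n$ is the grid argmin of $r(n)$.

## Cost elicitation from goal sampling

Per-observation costs rarely exist as money; the package infers them from
*goal sampling*: if a team accepts $n^{SATE}$ patients to reach a testing
target (say $\bar\beta \le 0.2$) and $n^{AMSE}$ patients for an estimation
target, then locally $c_n^{SATE} = -\,d\,\mathrm{SATE}(n)/dn$ at
$n^{SATE}$, and analogously for AMSE. The testing weight defaults to
$w = n^{SATE}/(n^{SATE} + n^{AMSE})$ — each target is as important as the
patients one would pay for it — which also brackets the optimal $n$
between $n^{SATE}$ and $n^{AMSE}$.

To make the estimation target concrete, the OC curves carry three monitors
averaged over the sampling prior truncated below at $\theta_R$: the
probability of an indeterminate outcome, and "extreme" ($1-\zeta$ quantile,
default $0.8$) losses of a hypothetical Phase III trial sized by the
one-sided z-formula at the Phase-II posterior mean: the power shortfall
versus a target (default 0.9), and the excess sample size versus sizing at
the true effect. Unsuccessful Phase-II outcomes realize power and sample
size 0, so their power loss is the full target and their sample-size gain
is minus the reference size; both enter the quantiles as-is. The Phase-III
significance level defaults to one-sided 0.025 and the planned size is
capped at $10^6$ (the z-formula diverges as the estimated effect approaches
$\theta_0$); both are configurable, since no single convention is canonical
for these monitors.

## Numerical design

Everything is deterministic quadrature and exact enumeration; no MCMC.

* **Binomial family.** Outcome spaces are enumerated exactly
  ($y = 0, \dots, n$), so conditional error rates, MSE and loss quantiles
  are finite sums.
* **Normal family.** All computation happens on the sufficient statistic
  $\bar y$. Decisions are evaluated pointwise on a fine grid (default 801
  nodes spanning the sampling prior's $10^{-8}$–$(1-10^{-8})$ quantile
  range widened by $9\sigma/\sqrt n$), with no assumption of a single
  critical value — adaptive priors can produce non-interval rejection
  regions. Region boundaries are then refined by root bracketing
  (`uniroot`, tolerance $10^{-12}$), so conditional rejection
  probabilities come from exact normal tail differences. Conditional MSE
  uses Gauss–Hermite quadrature (default order 199) with the posterior
  mean interpolated by a natural spline through the grid nodes; for
  single-component conjugate priors the posterior mean is linear in
  $\bar y$ and the interpolation is exact.
* **Sampling-prior averages** use Gauss–Legendre quadrature (default order
  199) on the truncated quantile range; beta sampling priors with
  $a_s \le 1$ have an unbounded density at 0 and are integrated after the
  substitution $\theta = u^{1/a_s}$.
* **Quantiles** over discrete outcome distributions use the
  left-continuous (type-1) inverse CDF.
* **EB power prior**: $a_0$ is selected on a 201-point grid with bounded
  scalar refinement; ties break toward smaller $a_0$ (less borrowing),
  because the marginal likelihood can be nearly flat in $a_0$ near the
  boundaries.
* Posterior tail probabilities feeding Bayes factors are evaluated on the
  log scale, so extreme outcomes (e.g. 25 successes out of 25) lose no
  accuracy.

### Differentiating sawtooth curves

Binomial OC curves are not smooth in $n$: the rejection boundary in $y$
moves by discrete jumps, so $\mathrm{SATE}(n)$ is a sawtooth of rising
ramps and sharp drops (period roughly 11 in the bundled proof-of-concept
scenario). A raw finite difference at a target $n$ is meaningless there,
and a *narrow* local fit only sees one ramp and returns a slope of the
wrong sign. `unit_cost(..., smooth = TRUE)` therefore smooths with a
tricube-weighted local quadratic whose window spans 75% of the grid by
default — wide enough to average over many sawtooth periods and recover
the declining trend — and the bundled binomial scenario computes its
elicitation curve on an extended grid ($n = 1, \dots, 300$) so the local
fit at $n^{SATE} = 21$ is supported from both sides. The AMSE curve decays
smoothly ($\approx$ like $1/n$), so its derivative is taken unsmoothed;
smoothing it with the same wide window would bias the slope badly, since a
quadratic cannot track $1/n$ curvature across half the grid. Normal-family
curves are smooth in $n$ and both derivatives are plain central
differences (grid step 2).

## The bundled scenarios

`trialrisk_scenarios()` lists two complete configurations used throughout
the examples and tests.

**`normal_vague`** — normal outcomes with $\sigma^2 = 1$, $\theta_0 = 0$,
$\theta_R = 0.15$, costs $c_0' = 0.05$, $c_1' = 0.95$. Historical
information (mean 0.25 from 50 observations) enters an informative
$N(0.25, 1/50)$ prior, a 50/50 robust mixture with a $N(0.25, 10^2)$
vague component, and an EB power prior over a $N(0, 10^2)$ baseline; the
sampling prior equals the informative prior. With the vague analysis prior,
$\bar\beta$ first drops below 0.2 at $n^{SATE} = 160$ (where
$\mathrm{SATE} = 0.027$), the estimation monitors are acceptable at
$n^{AMSE} = 180$ (where $\mathrm{AMSE} \le 0.006$), and the implied costs
are $c_n^{SATE} \approx 8.5\times10^{-5}$,
$c_n^{AMSE} \approx 3.1\times10^{-5}$, $w = 160/340 = 0.471$.

**`binomial_poc`** — a single-arm proof-of-concept trial on objective
response rate (non-small-cell lung cancer), $\theta_0 = 0.075$,
$\theta_R = 0.175$. The rate-matched RSN prior $Beta(0.0811, 1)$ has mean
0.075; the informative $Beta(11, 29)$ encodes 10 responses among 38
historical patients over a uniform baseline; the sampling prior is
$Beta(11, 29)$ (mean 0.275). The original design used $n = 25$ with a
fixed 95% posterior-probability rule, whose exact-enumeration power at
$\theta = 0.275$ is 0.858. Under the Bayes-factor rule, goal sampling gives
$n^{SATE} = 21$ ($\mathrm{SATE} = 0.058$) and $n^{AMSE} = 74$
($\mathrm{AMSE} = 0.0026$), $w = 21/95 = 0.221$, and risk minimization over
$n \le 150$ selects $n = 64$ — markedly more than the original 25, driven
by the estimation component and the wish to limit Phase-III power loss.

```{r binomial-pipeline, eval = FALSE}
sc <- load_scenario(trialrisk_scenarios("binomial_poc"))
run_scenario(sc, "reproduce")
```

(The pipeline takes a few tens of seconds; the same numbers are asserted
in the package's test suite and recomputed by `scripts/acceptance.R`.)

## What the scenarios do and do not establish

The bundled scenarios are analytic test beds, not data: outcomes enter
only through their sufficient-statistic distributions, which the conjugate
models describe exactly. Passing tests therefore certify the
decision-theoretic machinery — decisions, error-rate averaging, cost
algebra, optimization — under correctly specified models. They say nothing
about misspecification that real trials face: overdispersion, drift
between historical and current populations beyond a location shift,
non-exchangeable patients, or interim looks. Sensitivity scans over
sampling priors probe *parameter* conflict, not *model* conflict.

## Known limitations

* Conjugate normal (known variance) and binomial families only; no MCMC
  backend for non-conjugate likelihoods.
* One-sided composite hypotheses only; no point-null Bayes factors.
* Phase-III monitors use normal-approximation sample-size formulas, also
  for the binomial family; exact binomial sizing is out of scope.
* The sampling-cost term is linear in $n$; staged or nonlinear cost
  structures are not modeled.
* Cost elicitation differentiates numerically on the design grid; the
  derivative of a sawtooth trend is bandwidth-dependent, and the reported
  per-observation costs should be read to the ~10% accuracy that implies
  (the induced optimal $n$ is far more stable).
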