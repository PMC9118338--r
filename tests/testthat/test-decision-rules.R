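test_that("rejection thresholds follow the cost formulas", {
  hyp <- hypotheses(0.075, 0.175)
  cs <- cost_spec(0.05, 0.95)
  expect_equal(rejection_threshold(beta_prior(1, 1),
                                   cost_spec(0.05, 0.95, mode = "plain"),
                                   hyp), 0.05)
  # vague normal prior: mass below theta0 is ~0.5, threshold ~c0'/(c0'+c1')
  expect_equal(rejection_threshold(normal_prior(0, 100), cs,
                                   hypotheses(0, 0.15)),
               0.05, tolerance = 1e-6)
  # RSN prior closed form
  p <- 0.075^0.0811
  expect_equal(rejection_threshold(beta_prior(0.0811, 1), cs, hyp),
               0.05 * p / (0.05 * p + 0.95 * (1 - p)))
  # one-sided prior: undefined
  expect_error(rejection_threshold(point_prior(0.3), cs, hyp), "one side")
})

test_that("rejection threshold is increasing in cost ratio and null mass", {
  hyp <- hypotheses(0.075)
  ratios <- c(0.01, 0.05, 0.2, 1, 5)
  th <- vapply(ratios, function(r)
    rejection_threshold(beta_prior(2, 8), cost_spec(r, 1), hyp), 0)
  expect_true(all(diff(th) > 0))
  cs <- cost_spec(0.05, 0.95)
  priors <- list(beta_prior(1, 9), beta_prior(2, 8), beta_prior(5, 5),
                 beta_prior(8, 2))
  mass <- vapply(priors, prior_mass_below, 0, t = 0.075)
  th <- vapply(priors, rejection_threshold, 0, costs = cs, hyp = hyp)
  expect_true(all(diff(th[order(mass)]) > 0))
})

test_that("test decisions match closed-form benchmarks", {
  cs <- cost_spec(0.05, 0.95)
  mn <- trial_model("normal", 1)
  hn <- hypotheses(0, 0.15)
  # no data: BF = 1 >= c0'/c1', keep H0
  d0 <- decide_test(normal_prior(0.25, 1 / 50), mn, trial_data(0), cs, hn)
  expect_equal(d0$reject, 0L)
  expect_equal(exp(d0$log_bf), 1)
  # clear effect: posterior null prob ~ Phi(-3), reject
  d1 <- decide_test(normal_prior(0, 100), mn, trial_data(100, 0.3), cs, hn)
  expect_equal(d1$posterior_null_prob, pnorm(-3), tolerance = 1e-3)
  expect_equal(d1$reject, 1L)
  # binomial plain-threshold rule: rejection region is y >= 5 at n = 25
  m <- trial_model("binomial")
  hb <- hypotheses(0.075, 0.175)
  rej <- vapply(0:25, function(y)
    decide_test(beta_prior(0.0811, 1), m, trial_data(25, y),
                cost_spec(0.05, 0.95, mode = "plain"), hb)$reject, 0L)
  expect_equal(which(rej == 1L) - 1L, 5:25)
  # boundary tie keeps H0: symmetric posterior, threshold exactly 0.5
  dt <- decide_test(normal_prior(0, 100), mn, trial_data(0),
                    cost_spec(0.5, 0.5, mode = "plain"), hn)
  expect_equal(dt$reject, 0L)
})

test_that("Bayes factor matches truncated-marginal quadrature", {
  m <- trial_model("binomial")
  hyp <- hypotheses(0.075, 0.175)
  expect_equal(bayes_factor(beta_prior(2, 3), m, trial_data(0), hyp), 1)
  # all successes under a uniform prior: closed form via Beta(26, 1)
  bf <- bayes_factor(beta_prior(1, 1), m, trial_data(25, 25), hyp)
  q <- 0.075^26
  expect_equal(bf, (q / (1 - q)) * (0.925 / 0.075))
  # direct quadrature oracle on the truncated priors
  for (y in c(0, 3, 10)) {
    num <- integrate(function(t) dbinom(y, 25, t) * dbeta(t, 2, 3),
                     0, 0.075, rel.tol = 1e-12)$value / pbeta(0.075, 2, 3)
    den <- integrate(function(t) dbinom(y, 25, t) * dbeta(t, 2, 3),
                     0.075, 1, rel.tol = 1e-12)$value /
      (1 - pbeta(0.075, 2, 3))
    expect_equal(bayes_factor(beta_prior(2, 3), m, trial_data(25, y), hyp),
                 num / den, tolerance = 1e-8)
  }
  expect_error(bayes_factor(point_prior(0.3), m, trial_data(10, 3), hyp),
               "one side")
})

test_that("posterior-probability and Bayes-factor rules are equivalent", {
  # reweighted-cost rule rejects exactly when BF < c0'/c1', for every
  # outcome and all four analysis prior families
  bs <- binomial_setup()
  n <- 20
  for (pr in list(bs$rsn, bs$informative, bs$mixture, bs$eb)) {
    for (y in 0:n) {
      d <- trial_data(n, y)
      dec <- decide_test(pr, bs$model, d, bs$costs, bs$hyp)
      bf <- bayes_factor(pr, bs$model, d, bs$hyp)
      expect_identical(dec$reject == 1L, bf < 0.05 / 0.95)
    }
  }
  ns <- normal_setup()
  for (pr in list(ns$vague, ns$informative, ns$mixture, ns$eb)) {
    for (yb in seq(-0.4, 0.6, length.out = 41)) {
      d <- trial_data(80, yb)
      dec <- decide_test(pr, ns$model, d, ns$costs, ns$hyp)
      bf <- bayes_factor(pr, ns$model, d, ns$hyp)
      expect_identical(dec$reject == 1L, bf < 0.05 / 0.95)
    }
  }
})

test_that("vague-prior decision approaches the frequentist one-sided test", {
  mn <- trial_model("normal", 1)
  hn <- hypotheses(0)
  cs <- cost_spec(0.05, 0.95)
  pr <- normal_prior(0, 1e8) # sd 1e4
  n <- 50
  crit <- qnorm(0.95) / sqrt(n) # z-test critical mean at level 5%
  for (yb in crit + c(-0.05, -0.01, 0.01, 0.05)) {
    dec <- decide_test(pr, mn, trial_data(n, yb), cs, hn)
    expect_identical(dec$reject == 1L, yb > crit)
  }
})

test_that("outcome classification combines the two decisions", {
  expect_equal(classify_outcome(list(reject = 1L, relevant = 1L)),
               "success")
  expect_equal(classify_outcome(list(reject = 0L, relevant = 1L)),
               "indeterminate_relevant_only")
  expect_equal(classify_outcome(list(reject = 1L, relevant = 0L)),
               "indeterminate_significant_only")
  expect_equal(classify_outcome(list(reject = 0L, relevant = 0L)),
               "failure")
})

test_that("relevance requires the posterior median above thetaR", {
  mn <- trial_model("normal", 1)
  hyp <- hypotheses(0, 0.15)
  # posterior centered exactly at thetaR: not relevant (strict inequality)
  pr <- normal_prior(0.15, 1 / 50)
  expect_equal(decide_relevance(pr, mn, trial_data(0), hyp), 0L)
  # posterior N(0.2, 0.01): P(theta <= 0.15) = Phi(-0.5) < 0.5, relevant
  expect_equal(decide_relevance(normal_prior(0.2, 0.01), mn,
                                trial_data(0), hyp), 1L)
  expect_equal(decide_relevance(point_prior(0.3), mn, trial_data(0), hyp),
               1L)
})
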