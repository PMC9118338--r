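test_that("conjugate posterior updates match closed forms", {
  m <- trial_model("binomial")
  # uniform baseline + full historical data gives the informative prior
  pp <- power_prior(historical_data(38, successes = 10, failures = 28),
                    beta_prior(1, 1), a0 = 1)
  post <- posterior(pp, m, trial_data(0))
  expect_equal(post$a, 11)
  expect_equal(post$b, 29)

  post <- posterior(beta_prior(0.0811, 1), m, trial_data(25, 5))
  expect_equal(post$a, 5.0811)
  expect_equal(post$b, 21)

  mn <- trial_model("normal", 1)
  pr <- normal_prior(0.25, 1 / 50)
  expect_equal(posterior(pr, mn, trial_data(0)), pr)

  # equal prior and data precision: posterior mean at the midpoint
  pr <- normal_prior(0.1, 1 / 50)
  expect_equal(posterior_mean(pr, mn, trial_data(50, 0.3)), 0.2)
})

test_that("posterior tail probabilities match conjugate closed forms", {
  mn <- trial_model("normal", 1)
  expect_equal(posterior_tail_prob(normal_prior(0, 100), mn,
                                   trial_data(100, 0), 0),
               0.5, tolerance = 1e-4)
  # N(0.25, 1/50) prior, n = 50, ybar = 0.1 -> posterior N(0.175, 1/100)
  p <- posterior_tail_prob(normal_prior(0.25, 1 / 50), mn,
                           trial_data(50, 0.1), 0)
  expect_equal(p, pnorm(-0.175 / sqrt(1 / 100)))
  expect_equal(p, 0.0401, tolerance = 1e-2)
  expect_equal(posterior_tail_prob(point_prior(0.3), mn,
                                   trial_data(10, 0.1), 0), 0)
})

test_that("posterior tail and mean agree with Monte-Carlo sampling", {
  set.seed(42)
  m <- trial_model("binomial")
  pr <- beta_prior(0.0811, 1)
  d <- trial_data(25, 5)
  draws <- rbeta(1e5, 5.0811, 21)
  mc_tail <- mean(draws <= 0.075)
  se_tail <- sd(draws <= 0.075) / sqrt(1e5)
  expect_lt(abs(posterior_tail_prob(pr, m, d, 0.075) - mc_tail),
            3 * se_tail)
  expect_lt(abs(posterior_mean(pr, m, d) - mean(draws)),
            3 * sd(draws) / sqrt(1e5))
  expect_equal(posterior_mean(pr, m, d), 5.0811 / 26.0811)
})

test_that("posterior tail probability is monotone in the data", {
  mn <- trial_model("normal", 1)
  m <- trial_model("binomial")
  for (pr in list(normal_prior(0, 100), normal_prior(0.25, 1 / 50))) {
    tails <- vapply(seq(-0.5, 0.8, length.out = 40), function(yb)
      posterior_tail_prob(pr, mn, trial_data(60, yb), 0), 0)
    expect_true(all(diff(tails) <= 0))
  }
  for (pr in list(beta_prior(0.0811, 1), beta_prior(11, 29))) {
    tails <- vapply(0:30, function(y)
      posterior_tail_prob(pr, m, trial_data(30, y), 0.075), 0)
    expect_true(all(diff(tails) <= 0))
  }
})

test_that("mixture posteriors reweight by component marginal likelihood", {
  m <- trial_model("binomial")
  mx <- mixture_prior(list(beta_prior(11, 29), beta_prior(1, 1)),
                      c(0.5, 0.5))
  post <- posterior(mx, m, trial_data(20, 18)) # strong conflict with Beta(11,29)
  expect_equal(sum(post$weights), 1)
  expect_true(all(post$weights >= 0 & post$weights <= 1))
  expect_gt(post$weights[2], 0.99) # vague component dominates
  # weight-averaged tail probability
  t0 <- 0.3
  manual <- sum(post$weights * c(pbeta(t0, 29, 31), pbeta(t0, 19, 3)))
  expect_equal(prior_mass_below(post, t0), manual)
  # equal-weight mixture CDF is the average of the component CDFs
  expect_equal(prior_mass_below(mx, 0.2),
               (pbeta(0.2, 11, 29) + pbeta(0.2, 1, 1)) / 2)
})

test_that("prior_mass_below matches closed forms", {
  expect_equal(prior_mass_below(beta_prior(0.0811, 1), 0.075),
               0.075^0.0811)
  expect_equal(prior_mass_below(normal_prior(0, 100), 0), 0.5)
})

test_that("log marginal likelihoods normalize and match special cases", {
  m <- trial_model("binomial")
  # uniform prior: beta-binomial marginal is uniform over y
  lm_ <- vapply(0:25, function(y)
    log_marginal(beta_prior(1, 1), m, trial_data(25, y)), 0)
  expect_equal(lm_, rep(log(1 / 26), 26))
  # any proper prior: marginals sum to one over the outcome space
  for (pr in list(beta_prior(0.0811, 1), beta_prior(11, 29),
                  mixture_prior(list(beta_prior(11, 29), beta_prior(1, 1)),
                                c(0.5, 0.5)))) {
    tot <- sum(exp(vapply(0:20, function(y)
      log_marginal(pr, m, trial_data(20, y)), 0)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  # point-mass prior: marginal equals the likelihood
  expect_equal(log_marginal(point_prior(0.3), m, trial_data(20, 7)),
               dbinom(7, 20, 0.3, log = TRUE))
  # mixture marginal is the weight-average of component marginals
  mx <- mixture_prior(list(beta_prior(11, 29), beta_prior(1, 1)),
                      c(0.3, 0.7))
  d <- trial_data(15, 4)
  expect_equal(exp(log_marginal(mx, m, d)),
               0.3 * exp(log_marginal(beta_prior(11, 29), m, d)) +
                 0.7 * exp(log_marginal(beta_prior(1, 1), m, d)))
  # normal family: marginal density of ybar integrates to 1
  mn <- trial_model("normal", 1)
  f <- function(yb) vapply(yb, function(x)
    exp(log_marginal(normal_prior(0.25, 1 / 50), mn, trial_data(40, x))), 0)
  expect_equal(integrate(f, -3, 3, rel.tol = 1e-10)$value, 1,
               tolerance = 1e-7)
})

test_that("empirical-Bayes a0 tracks prior-data agreement", {
  mn <- trial_model("normal", 1)
  hd <- historical_data(50, mean = 0.25)
  base <- normal_prior(0, 100)
  # perfect agreement at large n: full borrowing
  expect_equal(eb_a0(hd, base, mn, trial_data(200, 0.25)), 1)
  # strong conflict: borrowing close to zero
  expect_lt(eb_a0(hd, base, mn, trial_data(200, -1)), 0.05)
  # dense-grid oracle agreement for a moderate-conflict case
  d <- trial_data(100, 0.1)
  grid <- seq(0, 1, length.out = 4001)
  lm_ <- vapply(grid, function(a)
    log_marginal(power_prior(hd, base, a), mn, d), 0)
  expect_equal(eb_a0(hd, base, mn, d), grid[which.max(lm_)],
               tolerance = 1e-3)
  # EB prior rejects empty data
  pp <- power_prior(hd, base, "empirical_bayes")
  expect_error(posterior(pp, mn, trial_data(0)), "marginal")
})

test_that("power prior endpoints reproduce baseline and full-data priors", {
  mn <- trial_model("normal", 1)
  hd <- historical_data(50, mean = 0.25)
  base <- normal_prior(0, 100)
  p0 <- posterior(power_prior(hd, base, 0), mn, trial_data(0))
  expect_equal(p0$mean, base$mean)
  expect_equal(p0$var, base$var)
  p1 <- posterior(power_prior(hd, base, 1), mn, trial_data(0))
  full <- posterior(base, mn, trial_data(50, 0.25))
  expect_equal(p1$mean, full$mean)
  expect_equal(p1$var, full$var)
  m <- trial_model("binomial")
  hdb <- historical_data(38, successes = 10, failures = 28)
  p1b <- posterior(power_prior(hdb, beta_prior(1, 1), 1), m, trial_data(0))
  expect_equal(c(p1b$a, p1b$b), c(11, 29))
})
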