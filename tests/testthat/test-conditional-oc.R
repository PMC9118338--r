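test_that("rejection profiles enumerate the decision regions", {
  bs <- binomial_setup()
  g <- outcome_grid(bs$model, 25)
  # plain 5% threshold: rejection region is y >= 5
  pr <- rejection_profile(bs$rsn, bs$model, 25,
                          cost_spec(0.05, 0.95, mode = "plain"), bs$hyp, g)
  expect_equal(pr$node[pr$reject == 1L], 5:25)
  # point-mass analysis prior: decisions independent of the data
  prp <- rejection_profile(point_prior(0.3), bs$model, 25,
                           cost_spec(0.05, 0.95, mode = "plain"), bs$hyp, g)
  expect_equal(length(unique(prp$reject)), 1L)
  expect_equal(length(unique(prp$relevant)), 1L)
  # single-component normal prior: rejection region is one upper half-line
  ns <- normal_setup()
  gn <- outcome_grid(ns$model, 100, theta_range = c(-0.5, 1))
  prn <- rejection_profile(ns$vague, ns$model, 100, ns$costs, ns$hyp, gn)
  iv <- attr(prn, "reject_intervals")
  expect_equal(nrow(iv), 1L)
  expect_equal(iv[1L, 2L], Inf)
  # the refined boundary matches the analytic critical value
  prec <- 1 / 100 + 100
  expect_equal(iv[1L, 1L], qnorm(0.95) * sqrt(prec) / 100,
               tolerance = 1e-6)
})

test_that("binomial conditional OCs agree with Monte-Carlo simulation", {
  set.seed(7)
  bs <- binomial_setup()
  n <- 25
  g <- outcome_grid(bs$model, n)
  pr <- rejection_profile(bs$rsn, bs$model, n, bs$costs, bs$hyp, g)
  nrep <- 1e5
  for (theta in c(0.05, 0.175, 0.275)) {
    y <- rbinom(nrep, n, theta)
    rej_mc <- mean(pr$reject[y + 1L])
    p <- p_exact <- sum(dbinom(pr$node[pr$reject == 1L], n, theta))
    se <- sqrt(p_exact * (1 - p_exact) / nrep)
    expect_lt(abs(rej_mc - p_exact), 3 * se + 1e-12)
    ind_nodes <- xor(pr$reject == 1L, pr$relevant == 1L)
    p_ind <- cond_indeterminate(theta, pr, g)
    se_i <- sqrt(p_ind * (1 - p_ind) / nrep)
    expect_lt(abs(mean(ind_nodes[y + 1L]) - p_ind), 3 * se_i + 1e-12)
  }
})

test_that("conditional error rates behave as rates", {
  bs <- binomial_setup()
  g <- outcome_grid(bs$model, 25)
  pr <- rejection_profile(bs$rsn, bs$model, 25, bs$costs, bs$hyp, g)
  # alpha(theta) is non-decreasing for a single-component prior
  th <- seq(0.005, 0.075, length.out = 30)
  a <- cond_error_rate(th, pr, g, bs$hyp)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= 1))
  # far-below-threshold effects are almost never rejected
  expect_lt(cond_error_rate(1e-4, pr, g, bs$hyp), 1e-6)
  # vague normal prior at theta0: rejection rate ~ c0'/(c0'+c1')
  ns <- normal_setup()
  gn <- outcome_grid(ns$model, 100, theta_range = c(-0.5, 1))
  prn <- rejection_profile(normal_prior(0, 1e6), ns$model, 100, ns$costs,
                           ns$hyp, gn)
  expect_equal(cond_error_rate(0, prn, gn, ns$hyp), 0.05,
               tolerance = 1e-3)
})

test_that("conditional MSE matches closed forms", {
  ns <- normal_setup()
  n <- 60
  # point-mass analysis prior: MSE is the squared distance to the mass point
  g <- outcome_grid(ns$model, n, theta_range = c(-0.5, 1))
  expect_equal(cond_mse(0.4, point_prior(0.3), ns$model, n, g), 0.01,
               tolerance = 1e-10)
  # conjugate normal prior: shrinkage bias^2 + shrunk sampling variance
  pr <- normal_prior(0.25, 1 / 50)
  prof <- rejection_profile(pr, ns$model, n, ns$costs, ns$hyp, g)
  for (theta in c(0, 0.15, 0.3)) {
    k <- n / (n + 50) # weight on the data
    closed <- ((1 - k) * (0.25 - theta))^2 + k^2 / n
    expect_equal(cond_mse(theta, pr, ns$model, n, g, prof), closed,
                 tolerance = 1e-8)
  }
  # vague prior: MSE ~ sigma^2 / n
  expect_equal(cond_mse(0.2, ns$vague, ns$model, n, g), 1 / n,
               tolerance = 1e-3)
})

test_that("indeterminate, success and failure probabilities sum to one", {
  bs <- binomial_setup()
  n <- 40
  g <- outcome_grid(bs$model, n)
  pr <- rejection_profile(bs$rsn, bs$model, n, bs$costs, bs$hyp, g)
  for (theta in c(0.05, 0.15, 0.3)) {
    mass <- dbinom(pr$node, n, theta)
    p_succ <- sum(mass[pr$reject == 1L & pr$relevant == 1L])
    p_fail <- sum(mass[pr$reject == 0L & pr$relevant == 0L])
    expect_equal(cond_indeterminate(theta, pr, g) + p_succ + p_fail, 1,
                 tolerance = 1e-12)
  }
  # degenerate profiles via a point-mass analysis prior (always/never)
  g25 <- outcome_grid(bs$model, 25)
  agree <- rejection_profile(point_prior(0.5), bs$model, 25,
                             cost_spec(0.05, 0.95, mode = "plain"),
                             bs$hyp, g25)
  expect_equal(unique(agree$reject), unique(agree$relevant))
  expect_equal(cond_indeterminate(0.2, agree, g25), 0)
})

test_that("Phase-III realized power and size follow the z-formula", {
  mn <- trial_model("normal", 1)
  hyp <- hypotheses(0, 0.15)
  p3 <- phase3_spec()
  # self-consistency: correct estimate realizes the target power
  r <- phase3_realized(0.3, TRUE, 0.3, mn, p3, hyp)
  expect_equal(r$realized_power, 0.9, tolerance = 1e-10)
  expect_equal(r$realized_n,
               ((qnorm(0.975) + qnorm(0.9)) / 0.3)^2)
  # no success: the confirmatory trial does not take place
  expect_equal(phase3_realized(0.3, FALSE, 0.3, mn, p3, hyp),
               list(realized_power = 0, realized_n = 0))
  # overestimated effect: underpowered Phase III
  expect_lt(phase3_realized(0.4, TRUE, 0.3, mn, p3, hyp)$realized_power,
            0.9)
  # estimate at or below theta0: planned size capped
  expect_equal(phase3_realized(0, TRUE, 0.3, mn, p3, hyp)$realized_n, 1e6)
  # binomial variant uses p(1-p) variances
  mb <- trial_model("binomial")
  rb <- phase3_realized(0.275, TRUE, 0.275, mb, p3, hypotheses(0.075))
  expect_equal(rb$realized_power, 0.9, tolerance = 1e-10)
  expect_equal(rb$realized_n,
               (qnorm(0.975) + qnorm(0.9))^2 * 0.275 * 0.725 / 0.2^2)
})

test_that("conditional loss quantiles cover the degenerate regimes", {
  mn <- trial_model("normal", 1)
  hyp <- hypotheses(0, 0.15)
  p3 <- phase3_spec()
  cs <- cost_spec(0.05, 0.95)
  theta <- 0.3
  g <- outcome_grid(mn, 50, theta_range = c(-0.3, 0.9))
  # point-mass analysis prior at theta: every outcome is a success with a
  # perfect estimate, so both extreme losses are zero
  pr <- rejection_profile(point_prior(theta), mn, 50,
                          cost_spec(0.05, 0.95, mode = "plain"), hyp, g)
  expect_equal(unique(pr$reject), 1L)
  lq <- cond_loss_quantiles(theta, point_prior(theta), mn, 50, pr, g, p3,
                            hyp)
  expect_equal(lq$extreme_power_loss, 0)
  expect_equal(lq$extreme_n_gain, 0)
  # point mass below theta0: never successful, loss is the full target power
  pr0 <- rejection_profile(point_prior(-1), mn, 50,
                           cost_spec(0.05, 0.95, mode = "plain"), hyp, g)
  expect_equal(unique(pr0$reject), 0L)
  lq0 <- cond_loss_quantiles(theta, point_prior(-1), mn, 50, pr0, g, p3,
                             hyp)
  expect_equal(lq0$extreme_power_loss, p3$target_power)
})
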