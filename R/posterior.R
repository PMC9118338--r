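#' Posterior distribution under a conjugate analysis prior
#'
#' Updates the analysis prior with the observed data. The posterior stays in
#' the prior's representational family: normal priors get the
#' precision-weighted update, beta priors become `Beta(a + y, b + n - y)`,
#' mixtures update each component and reweight by component marginal
#' likelihoods, and power priors are first resolved to their concrete
#' conjugate form (choosing `a0` by empirical Bayes when so flagged).
#'
#' @param prior A [`trial_prior`][priors].
#' @param model A [trial_model()].
#' @param data A [trial_data()]; `n = 0` returns the (resolved) prior.
#' @return A [`trial_prior`][priors] representing the posterior.
#' @examples
#' posterior(beta_prior(0.0811, 1), trial_model("binomial"), trial_data(25, 5))
#' @export
posterior <- function(prior, model, data) {
  check_data(model, data)
  prior <- resolve_prior(prior, model, data)
  if (data$n == 0) return(prior)
  switch(prior$variant,
    normal = {
      prec <- 1 / prior$var + data$n / model$sigma2
      mu <- (prior$mean / prior$var +
               data$n * data$stat / model$sigma2) / prec
      normal_prior(mu, 1 / prec)
    },
    beta = beta_prior(prior$a + data$stat,
                      prior$b + data$n - data$stat),
    point = prior,
    mixture = {
      post <- lapply(prior$components, posterior, model = model, data = data)
      lm_ <- vapply(prior$components, log_marginal, 0,
                    model = model, data = data)
      lw <- log(prior$weights) + lm_
      mixture_prior(post, exp(lw - logsumexp(lw)))
    })
}

#' Posterior tail probability \eqn{P(\theta \le t \mid y)}
#'
#' The posterior probability of the (one-sided) null hypothesis when
#' `t = theta0`; also used for the relevance criterion at `t = thetaR`.
#'
#' @inheritParams posterior
#' @param t Threshold.
#' @param lower.tail,log.p Passed to the underlying CDF; extreme tails are
#'   evaluated on the log scale without underflow.
#' @return A probability (or its log).
#' @export
posterior_tail_prob <- function(prior, model, data, t,
                                lower.tail = TRUE, log.p = FALSE) {
  prior_cdf(posterior(prior, model, data), t,
            lower.tail = lower.tail, log.p = log.p)
}

#' Posterior mean \eqn{E(\theta \mid y)}
#'
#' The Bayes estimator under quadratic loss; this is the estimate whose
#' frequentist mean squared error enters the integrated risk, and the
#' effect estimate carried into Phase-III sample-size calculations.
#'
#' @inheritParams posterior
#' @return A real number.
#' @export
posterior_mean <- function(prior, model, data) {
  prior_mean_value(posterior(prior, model, data))
}

#' Log marginal likelihood (prior predictive) of the data
#'
#' \eqn{\log m(y) = \log \int f(y \mid n, \theta)\, \pi(\theta)\, d\theta},
#' evaluated on the sufficient statistic: a normal predictive for the normal
#' family, a beta-binomial predictive for the binomial family, the
#' log-likelihood at the support point for point-mass priors, and a
#' log-sum-exp of weighted component marginals for mixtures.
#'
#' @inheritParams posterior
#' @return Log marginal likelihood (log density of \eqn{\bar{y}}, or log
#'   probability of the success count).
#' @export
log_marginal <- function(prior, model, data) {
  check_data(model, data)
  if (data$n == 0) stop("the marginal likelihood is undefined without data")
  prior <- resolve_prior(prior, model, data)
  switch(prior$variant,
    normal = stats::dnorm(data$stat, prior$mean,
                          sqrt(prior$var + model$sigma2 / data$n), log = TRUE),
    beta = lchoose(data$n, data$stat) +
      lbeta(prior$a + data$stat, prior$b + data$n - data$stat) -
      lbeta(prior$a, prior$b),
    point = if (model$family == "normal") {
      stats::dnorm(data$stat, prior$location,
                   sqrt(model$sigma2 / data$n), log = TRUE)
    } else {
      stats::dbinom(data$stat, data$n, prior$location, log = TRUE)
    },
    mixture = logsumexp(log(prior$weights) +
                          vapply(prior$components, log_marginal, 0,
                                 model = model, data = data)))
}

#' Empirical-Bayes selection of the power-prior weight
#'
#' Chooses the historical-data discounting weight \eqn{a_0 \in [0, 1]} by
#' maximizing the marginal likelihood of the current data under the
#' \eqn{a_0}-power prior. The search is a 201-point grid on `[0, 1]`
#' followed by bounded scalar refinement around the best grid cell; the
#' marginal in \eqn{a_0} can be flat near the boundaries, and ties are
#' broken toward smaller \eqn{a_0} (less borrowing).
#'
#' @param historical A [historical_data()] summary.
#' @param baseline Baseline prior of the power prior.
#' @param model A [trial_model()].
#' @param data Current [trial_data()] with `n >= 1`.
#' @return The selected \eqn{a_0}.
#' @export
eb_a0 <- function(historical, baseline, model, data) {
  check_data(model, data)
  if (data$n < 1)
    stop("empirical-Bayes a0 selection needs current data (n >= 1)")
  obj <- function(a0) {
    vapply(a0, function(a) {
      log_marginal(apply_power(historical, baseline, a, model), model, data)
    }, 0)
  }
  grid <- seq(0, 1, length.out = 201L)
  lm_ <- obj(grid)
  i <- which.max(lm_) # first max = smallest a0 on ties
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  # prefer the smaller candidate when the refinement gains nothing
  if (opt$objective > lm_[i] + 1e-12) opt$maximum else grid[i]
}
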