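#' Hypothesis thresholds
#'
#' One-sided hypotheses \eqn{H_0: \theta \le \theta_0} versus
#' \eqn{H_1: \theta > \theta_0}, with an additional relevance threshold
#' \eqn{\theta_R \ge \theta_0} above which an effect is considered large
#' enough to carry into a confirmatory trial.
#'
#' @param theta0 Significance threshold \eqn{\theta_0}.
#' @param thetaR Relevance threshold \eqn{\theta_R} (defaults to `theta0`).
#' @return An object of class `hypotheses`.
#' @examples
#' hypotheses(0, 0.15)
#' @export
hypotheses <- function(theta0, thetaR = theta0) {
  stopifnot(is.numeric(theta0), is.numeric(thetaR), thetaR >= theta0)
  structure(list(theta0 = theta0, thetaR = thetaR), class = "hypotheses")
}

#' Test-error cost specification
#'
#' `c0p` (\eqn{c_0'}) is the cost of a false negative (keeping \eqn{H_0}
#' when the effect is real), `c1p` (\eqn{c_1'}) the cost of a false
#' positive. In mode `"bf_reweighted"` the working costs are inflated by the
#' inverse prior hypothesis masses, \eqn{c_0 = c_0'/P^{\pi}(\theta >
#' \theta_0)} and \eqn{c_1 = c_1'/P^{\pi}(\theta \le \theta_0)}, which makes
#' the rejection rule a pure Bayes-factor threshold at \eqn{c_0'/c_1'} and
#' the integrated risk a weighted sum of *average* error rates. Mode
#' `"plain"` uses the fixed threshold \eqn{c_0'/(c_0'+c_1')} regardless of
#' the prior.
#'
#' @param c0p,c1p Positive costs; conventionally `c0p + c1p = 1`.
#' @param mode `"bf_reweighted"` or `"plain"`.
#' @param normalize If `TRUE`, rescale so that `c0p + c1p = 1`.
#' @return An object of class `cost_spec`.
#' @examples
#' cost_spec(0.05, 0.95)
#' @export
cost_spec <- function(c0p = 0.05, c1p = 0.95,
                      mode = c("bf_reweighted", "plain"),
                      normalize = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(c0p), is.numeric(c1p), c0p > 0, c1p > 0)
  if (normalize) {
    s <- c0p + c1p
    c0p <- c0p / s
    c1p <- c1p / s
  }
  structure(list(c0p = c0p, c1p = c1p, mode = mode), class = "cost_spec")
}

#' Rejection threshold for the posterior probability of the null
#'
#' In `"bf_reweighted"` mode the threshold is
#' \deqn{\gamma^{\pi} = \frac{c_0' P^{\pi}(\theta \le \theta_0)}
#'   {c_0' P^{\pi}(\theta \le \theta_0) + c_1' (1 - P^{\pi}(\theta \le \theta_0))},}
#' so that rejecting when \eqn{P^{\pi}(\theta \le \theta_0 | y) < \gamma^\pi}
#' is the same as rejecting when the Bayes factor falls below
#' \eqn{c_0'/c_1'}. In `"plain"` mode it is the prior-free
#' \eqn{c_0'/(c_0'+c_1')}.
#'
#' For data-dependent priors (empirical-Bayes power priors) the threshold
#' depends on the observed data; pass `model` and `data` so the prior can be
#' resolved.
#'
#' @param prior Analysis prior.
#' @param costs A [cost_spec()].
#' @param hyp A [hypotheses()].
#' @param model,data Needed only to resolve data-dependent priors.
#' @return The threshold \eqn{\gamma^{\pi}} in `(0, 1)`.
#' @examples
#' rejection_threshold(beta_prior(0.0811, 1), cost_spec(0.05, 0.95),
#'                     hypotheses(0.075, 0.175))
#' @export
rejection_threshold <- function(prior, costs, hyp, model = NULL, data = NULL) {
  if (costs$mode == "plain") return(costs$c0p / (costs$c0p + costs$c1p))
  prior <- resolve_prior(prior, model, data)
  p0 <- prior_cdf(prior, hyp$theta0)
  if (p0 <= 0 || p0 >= 1)
    stop("prior mass lies entirely on one side of theta0; the ",
         "cost-reweighted threshold is undefined")
  costs$c0p * p0 / (costs$c0p * p0 + costs$c1p * (1 - p0))
}

#' Bayes factor for the one-sided hypotheses
#'
#' The Bayes factor of \eqn{H_0: \theta \le \theta_0} versus
#' \eqn{H_1: \theta > \theta_0} is the ratio of marginal likelihoods under
#' the prior truncated-and-renormalized to each hypothesis. It is computed
#' through the posterior/prior odds identity
#' \deqn{BF(y) = \frac{P(\theta \le \theta_0 | y) / P(\theta > \theta_0 | y)}
#'   {P(\theta \le \theta_0) / P(\theta > \theta_0)},}
#' with tails evaluated on the log scale so extreme outcomes (e.g. all
#' successes) retain accuracy. Keeping \eqn{H_0} when
#' \eqn{c_0'/c_1' \le BF(y)} minimizes the weighted sum of average error
#' rates.
#'
#' @inheritParams posterior
#' @param hyp A [hypotheses()].
#' @param log If `TRUE`, return \eqn{\log BF}.
#' @return The Bayes factor (or its log).
#' @export
bayes_factor <- function(prior, model, data, hyp, log = FALSE) {
  rp <- resolve_prior(prior, model, data)
  lp0 <- prior_cdf(rp, hyp$theta0, log.p = TRUE)
  lp1 <- prior_cdf(rp, hyp$theta0, lower.tail = FALSE, log.p = TRUE)
  if (!is.finite(lp0) || !is.finite(lp1))
    stop("prior mass lies entirely on one side of theta0; ",
         "the one-sided Bayes factor is undefined")
  post <- posterior(rp, model, data)
  lq0 <- prior_cdf(post, hyp$theta0, log.p = TRUE)
  lq1 <- prior_cdf(post, hyp$theta0, lower.tail = FALSE, log.p = TRUE)
  lbf <- (lq0 - lq1) - (lp0 - lp1)
  if (log) lbf else exp(lbf)
}

#' Cost-optimal test decision
#'
#' Rejects \eqn{H_0} when the posterior probability of the null falls
#' strictly below the rejection threshold; ties keep \eqn{H_0} (the
#' Bayes-factor form keeps \eqn{H_0} when \eqn{c_0'/c_1' \le BF}). For
#' data-dependent priors both the posterior probability and the threshold
#' are recomputed from the resolved, per-dataset prior.
#'
#' @inheritParams posterior
#' @param costs A [cost_spec()].
#' @param hyp A [hypotheses()].
#' @return An object of class `test_decision` with fields `reject`,
#'   `relevant`, `threshold`, `posterior_null_prob`, `log_bf`.
#' @examples
#' decide_test(normal_prior(0, 100), trial_model("normal", 1),
#'             trial_data(100, 0.3), cost_spec(0.05, 0.95), hypotheses(0, 0.15))
#' @export
decide_test <- function(prior, model, data, costs, hyp) {
  rp <- resolve_prior(prior, model, data)
  gamma <- rejection_threshold(rp, costs, hyp)
  post <- posterior(rp, model, data)
  p0 <- prior_cdf(post, hyp$theta0)
  lbf <- tryCatch(bayes_factor(rp, model, data, hyp, log = TRUE),
                  error = function(e) NA_real_)
  structure(list(reject = as.integer(p0 < gamma),
                 relevant = as.integer(prior_cdf(post, hyp$thetaR) < 0.5),
                 threshold = gamma,
                 posterior_null_prob = p0,
                 log_bf = lbf),
            class = "test_decision")
}

#' Relevance decision
#'
#' A trial outcome is "relevant" when the posterior median exceeds the
#' relevance threshold, i.e. \eqn{P^{\pi_a}(\theta \le \theta_R | y) < 0.5}
#' (strict: a posterior centered exactly at \eqn{\theta_R} is not relevant).
#'
#' @inheritParams decide_test
#' @return `1L` if relevant, else `0L`.
#' @export
decide_relevance <- function(prior, model, data, hyp) {
  as.integer(posterior_tail_prob(prior, model, data, hyp$thetaR) < 0.5)
}

#' Classify a trial outcome from its two decisions
#'
#' A trial is a *success* when both significance and relevance are declared,
#' a *failure* when neither is, and *indeterminate* when exactly one is
#' (split by which one).
#'
#' @param decision A `test_decision`, or anything with `reject` and
#'   `relevant` components.
#' @return One of `"success"`, `"indeterminate_significant_only"`,
#'   `"indeterminate_relevant_only"`, `"failure"`.
#' @export
classify_outcome <- function(decision) {
  r <- decision$reject
  v <- decision$relevant
  stopifnot(!is.null(r), !is.null(v))
  if (r && v) "success"
  else if (r) "indeterminate_significant_only"
  else if (v) "indeterminate_relevant_only"
  else "failure"
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf(
    "<test_decision> %s (P(H0|y) = %.4g vs threshold %.4g), %s, log BF = %.4g\n",
    if (x$reject) "reject H0" else "keep H0",
    x$posterior_null_prob, x$threshold,
    if (x$relevant) "relevant" else "not relevant", x$log_bf))
  invisible(x)
}
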