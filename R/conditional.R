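#' Outcome grid for conditional operating characteristics
#'
#' The outcome space over which decisions are enumerated: all success counts
#' `0..n` for the binomial family (conditional quantities are then exact
#' sums), or a fine regular grid of sample means for the normal family. The
#' normal grid spans `theta_range` widened by `pad` standard deviations of
#' \eqn{\bar{y}}, so that every true \eqn{\theta} of interest keeps
#' essentially all its outcome mass inside the grid.
#'
#' @param model A [trial_model()].
#' @param n Sample size.
#' @param theta_range Range of true-effect values the grid must cover
#'   (normal family only).
#' @param nodes Number of grid nodes (normal family only).
#' @param pad Half-width of the extension, in units of
#'   \eqn{\sigma/\sqrt{n}}.
#' @return An object of class `outcome_grid`.
#' @export
outcome_grid <- function(model, n, theta_range = NULL, nodes = 801L,
                         pad = 9) {
  stopifnot(n >= 1)
  if (model$family == "binomial") {
    structure(list(family = "binomial", n = n, nodes = 0:n),
              class = "outcome_grid")
  } else {
    if (is.null(theta_range))
      stop("'theta_range' is required for the normal family")
    s <- sqrt(model$sigma2 / n)
    xs <- seq(min(theta_range) - pad * s, max(theta_range) + pad * s,
              length.out = nodes)
    structure(list(family = "normal", n = n, nodes = xs, sd = s),
              class = "outcome_grid")
  }
}

## Vectorized per-node decision quantities. For priors that do not depend on
## the data the conjugate forms are evaluated in closed form across all
## nodes; empirical-Bayes power priors fall back to a per-node resolve.
profile_eval <- function(prior, model, n, costs, hyp, nodes) {
  if (is_data_dependent(prior)) {
    res <- vapply(nodes, function(x) {
      d <- trial_data(n, x)
      rp <- resolve_prior(prior, model, d)
      post <- posterior(rp, model, d)
      c(prior_cdf(post, hyp$theta0), prior_cdf(post, hyp$thetaR),
        prior_mean_value(post),
        rejection_threshold(rp, costs, hyp))
    }, numeric(4L))
    list(tail0 = res[1L, ], tailR = res[2L, ], postmean = res[3L, ],
         gamma = res[4L, ])
  } else {
    rp <- resolve_prior(prior, model)
    gamma <- rejection_threshold(rp, costs, hyp)
    pe <- post_eval_vec(rp, model, n, nodes, hyp)
    c(pe, list(gamma = rep(gamma, length(nodes))))
  }
}

post_eval_vec <- function(prior, model, n, nodes, hyp) {
  switch(prior$variant,
    normal = {
      prec <- 1 / prior$var + n / model$sigma2
      mu <- (prior$mean / prior$var + n * nodes / model$sigma2) / prec
      sd_ <- sqrt(1 / prec)
      list(tail0 = stats::pnorm(hyp$theta0, mu, sd_),
           tailR = stats::pnorm(hyp$thetaR, mu, sd_),
           postmean = mu)
    },
    beta = {
      a <- prior$a + nodes
      b <- prior$b + n - nodes
      list(tail0 = stats::pbeta(hyp$theta0, a, b),
           tailR = stats::pbeta(hyp$thetaR, a, b),
           postmean = a / (a + b))
    },
    point = {
      k <- length(nodes)
      list(tail0 = rep(as.numeric(prior$location <= hyp$theta0), k),
           tailR = rep(as.numeric(prior$location <= hyp$thetaR), k),
           postmean = rep(prior$location, k))
    },
    mixture = {
      parts <- lapply(prior$components, post_eval_vec,
                      model = model, n = n, nodes = nodes, hyp = hyp)
      lm_ <- vapply(prior$components, function(cp) {
        vapply(nodes, function(x)
          log_marginal(cp, model, trial_data(n, x)), 0)
      }, numeric(length(nodes)))
      lw <- sweep(matrix(lm_, nrow = length(nodes)), 2L,
                  log(prior$weights), "+")
      w <- exp(lw - apply(lw, 1L, logsumexp)) # posterior mixture weights
      comb <- function(field) {
        rowSums(w * vapply(parts, `[[`, numeric(length(nodes)), field))
      }
      list(tail0 = comb("tail0"), tailR = comb("tailR"),
           postmean = comb("postmean"))
    },
    stop("unsupported prior variant in profile evaluation"))
}

#' Rejection and relevance profile over the outcome space
#'
#' Evaluates the test decision, the relevance decision, and the posterior
#' mean at every node of the outcome grid. Decisions are taken pointwise
#' with no monotonicity assumption: adaptive priors (mixtures, EB power
#' priors) can induce non-interval rejection regions. For the normal family
#' the decision boundaries are additionally refined by root bracketing, so
#' conditional rejection probabilities are later evaluated from exact normal
#' tail differences rather than grid sums.
#'
#' @inheritParams decide_test
#' @param n Sample size the profile is built for.
#' @param grid An [outcome_grid()] built for the same `n`.
#' @return An object of class `rejection_profile`: a data frame with columns
#'   `node`, `reject`, `relevant`, `post_mean` and (normal family)
#'   attributes holding the refined decision intervals.
#' @export
rejection_profile <- function(prior, model, n, costs, hyp, grid) {
  stopifnot(inherits(grid, "outcome_grid"), grid$n == n)
  pe <- profile_eval(prior, model, n, costs, hyp, grid$nodes)
  reject <- pe$tail0 < pe$gamma
  relevant <- pe$tailR < 0.5
  out <- data.frame(node = grid$nodes, reject = as.integer(reject),
                    relevant = as.integer(relevant), post_mean = pe$postmean)
  class(out) <- c("rejection_profile", "data.frame")
  attr(out, "family") <- grid$family
  attr(out, "n") <- n
  if (grid$family == "normal") {
    h_rej <- function(x) {
      e <- profile_eval(prior, model, n, costs, hyp, x)
      e$tail0 - e$gamma
    }
    h_rel <- function(x) {
      e <- profile_eval(prior, model, n, costs, hyp, x)
      e$tailR - 0.5
    }
    attr(out, "sd") <- grid$sd
    attr(out, "reject_intervals") <-
      refine_intervals(grid$nodes, pe$tail0 - pe$gamma, h_rej)
    attr(out, "relevant_intervals") <-
      refine_intervals(grid$nodes, pe$tailR - 0.5, h_rel)
    attr(out, "postmean_fun") <-
      stats::splinefun(grid$nodes, pe$postmean, method = "natural")
  }
  out
}

## Turn the sign pattern of h (negative = inside the region) on a grid into
## a set of intervals with uniroot-refined endpoints.
refine_intervals <- function(nodes, h, hfun) {
  inside <- h < 0
  if (!any(inside)) return(matrix(numeric(0), ncol = 2L))
  d <- diff(inside)
  starts <- which(d == 1L) # boundary between i and i+1: entering
  ends <- which(d == -1L)  # leaving
  lo <- if (inside[1L]) -Inf else NULL
  bounds_lo <- c(lo, vapply(starts, function(i) {
    stats::uniroot(hfun, lower = nodes[i], upper = nodes[i + 1L],
                   tol = 1e-12)$root
  }, 0))
  hi <- if (inside[length(inside)]) Inf else NULL
  bounds_hi <- c(vapply(ends, function(i) {
    stats::uniroot(hfun, lower = nodes[i], upper = nodes[i + 1L],
                   tol = 1e-12)$root
  }, 0), hi)
  cbind(bounds_lo, bounds_hi, deparse.level = 0)
}

## P(ybar in intervals | theta) for the normal family.
interval_prob <- function(intervals, theta, sd) {
  if (nrow(intervals) == 0L) return(rep(0, length(theta)))
  p <- 0
  for (k in seq_len(nrow(intervals))) {
    p <- p + stats::pnorm((intervals[k, 2L] - theta) / sd) -
      stats::pnorm((intervals[k, 1L] - theta) / sd)
  }
  p
}

intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(numeric(0), ncol = 2L))
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1L], b[j, 1L])
    hi <- min(a[i, 2L], b[j, 2L])
    if (lo < hi) out <- rbind(out, c(lo, hi))
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2L) else out
}

## P(reject | theta), vectorized over theta.
p_reject <- function(theta, profile, grid) {
  if (grid$family == "binomial") {
    R <- profile$node[profile$reject == 1L]
    vapply(theta, function(t) sum(stats::dbinom(R, grid$n, t)), 0)
  } else {
    interval_prob(attr(profile, "reject_intervals"), theta,
                  attr(profile, "sd"))
  }
}

#' Conditional test error rate at a fixed true effect
#'
#' Returns the type I error rate \eqn{\alpha(\theta) = P(\mathrm{reject}
#' \mid \theta)} when \eqn{\theta \le \theta_0}, and the type II error rate
#' \eqn{\beta(\theta) = 1 - P(\mathrm{reject} \mid \theta)} otherwise.
#' Binomial probabilities are exact enumeration sums; normal ones are exact
#' tail differences over the refined rejection intervals.
#'
#' @param theta True effect (vectorized).
#' @param profile A [rejection_profile()].
#' @param grid The [outcome_grid()] the profile was built on.
#' @param hyp A [hypotheses()].
#' @return Error rate(s) in `[0, 1]`.
#' @export
cond_error_rate <- function(theta, profile, grid, hyp) {
  pr <- p_reject(theta, profile, grid)
  ifelse(theta <= hyp$theta0, pr, 1 - pr)
}

#' Conditional MSE of the posterior-mean estimator
#'
#' \eqn{MSE(\theta) = E^f[\{\theta - E(\theta \mid y)\}^2]}: an exact sum
#' over outcomes for the binomial family, Gauss-Hermite quadrature over
#' \eqn{\bar{y} \sim N(\theta, \sigma^2/n)} for the normal family. When a
#' profile is supplied its interpolated posterior-mean function is reused;
#' otherwise the posterior mean is evaluated directly at the quadrature
#' nodes.
#'
#' @inheritParams cond_error_rate
#' @param prior Analysis prior.
#' @param model A [trial_model()].
#' @param n Sample size.
#' @param gh_order Gauss-Hermite order (normal family).
#' @return MSE value(s), nonnegative.
#' @export
cond_mse <- function(theta, prior, model, n, grid = NULL, profile = NULL,
                     gh_order = 199L) {
  if (model$family == "binomial") {
    y <- 0:n
    pm <- if (!is.null(profile)) profile$post_mean else
      post_eval_vec(resolve_prior(prior, model), model, n, y,
                    hypotheses(0))$postmean
    vapply(theta, function(t)
      sum(stats::dbinom(y, n, t) * (t - pm)^2), 0)
  } else {
    gh <- gauss_hermite(gh_order)
    s <- sqrt(model$sigma2 / n)
    pmf <- if (!is.null(profile)) attr(profile, "postmean_fun") else {
      rp <- resolve_prior(prior, model)
      function(x) post_eval_vec(rp, model, n, x, hypotheses(0))$postmean
    }
    vapply(theta, function(t) {
      yb <- t + sqrt(2) * s * gh$x
      sum(gh$w * (t - pmf(yb))^2) / sqrt(pi)
    }, 0)
  }
}

#' Conditional probability of an indeterminate outcome
#'
#' Probability that exactly one of significance and relevance is declared at
#' a fixed true effect.
#'
#' @inheritParams cond_error_rate
#' @return Probability value(s).
#' @export
cond_indeterminate <- function(theta, profile, grid) {
  if (grid$family == "binomial") {
    ind <- xor(profile$reject == 1L, profile$relevant == 1L)
    Y <- profile$node[ind]
    vapply(theta, function(t) sum(stats::dbinom(Y, grid$n, t)), 0)
  } else {
    sd_ <- attr(profile, "sd")
    R <- attr(profile, "reject_intervals")
    V <- attr(profile, "relevant_intervals")
    interval_prob(R, theta, sd_) + interval_prob(V, theta, sd_) -
      2 * interval_prob(intersect_intervals(R, V), theta, sd_)
  }
}

#' Phase-III planning parameters
#'
#' @param target_power Planned power of the confirmatory trial.
#' @param alpha3 One-sided significance level of the confirmatory trial.
#' @param zeta Tail level: "extreme" losses are the \eqn{(1-\zeta)}
#'   quantiles of the conditional loss distributions.
#' @param n_cap Ceiling for the planned sample size when the estimated
#'   effect is at or below `theta0` (the sample-size formula diverges there).
#' @return An object of class `phase3_spec`.
#' @export
phase3_spec <- function(target_power = 0.9, alpha3 = 0.025, zeta = 0.2,
                        n_cap = 1e6) {
  stopifnot(target_power > 0, target_power < 1, alpha3 > 0, alpha3 < 0.5,
            zeta > 0, zeta < 1, n_cap > 0)
  structure(list(target_power = target_power, alpha3 = alpha3, zeta = zeta,
                 n_cap = n_cap), class = "phase3_spec")
}

## One-sided z-formula planning size at effect (est - theta0); variance is
## sigma^2 for the normal family and p(1-p) at `pvar` for the binomial.
plan_n <- function(delta, varhat, spec) {
  z <- stats::qnorm(1 - spec$alpha3) + stats::qnorm(spec$target_power)
  pmin(spec$n_cap, z^2 * varhat / pmax(delta, 0)^2)
}

#' Realized Phase-III power and sample size for one Phase-II outcome
#'
#' If the Phase-II trial is a success, the Phase-III trial is sized by the
#' standard one-sided z-formula taking the Phase-II posterior mean as the
#' true effect; the realized power is the power of that trial at the actual
#' true effect. If the Phase-II outcome is not a success, the confirmatory
#' trial does not take place and both realized quantities are 0.
#'
#' @param post_mean Phase-II posterior mean \eqn{\hat\theta}.
#' @param success 1 if the Phase-II outcome is classified a success.
#' @param theta_true The actual true effect.
#' @param model A [trial_model()].
#' @param spec A [phase3_spec()].
#' @param hyp A [hypotheses()] (supplies \eqn{\theta_0}).
#' @return `list(realized_power, realized_n)`.
#' @export
phase3_realized <- function(post_mean, success, theta_true, model, spec,
                            hyp) {
  if (!success) return(list(realized_power = 0, realized_n = 0))
  varhat <- if (model$family == "normal") model$sigma2 else
    post_mean * (1 - post_mean)
  n3 <- plan_n(post_mean - hyp$theta0, varhat, spec)
  vart <- if (model$family == "normal") model$sigma2 else
    theta_true * (1 - theta_true)
  pow <- stats::pnorm((theta_true - hyp$theta0) * sqrt(n3) / sqrt(vart) -
                        stats::qnorm(1 - spec$alpha3))
  list(realized_power = pow, realized_n = n3)
}

#' Conditional extreme power loss and sample-size gain
#'
#' For every Phase-II outcome, the power loss is the target Phase-III power
#' minus the realized power, and the sample-size gain is the realized
#' Phase-III size minus the size that would be planned at the true effect.
#' Unsuccessful outcomes realize 0 power and 0 samples, so their loss is the
#' full target power and their gain is minus the reference size. The
#' function returns the \eqn{(1-\zeta)} quantiles (left-continuous, type-1)
#' of both loss distributions under the outcome distribution at `theta`.
#'
#' @inheritParams cond_mse
#' @param profile A [rejection_profile()].
#' @param grid The matching [outcome_grid()].
#' @param spec A [phase3_spec()].
#' @param hyp A [hypotheses()].
#' @return `list(extreme_power_loss, extreme_n_gain)`.
#' @export
cond_loss_quantiles <- function(theta, prior, model, n, profile, grid, spec,
                                hyp) {
  stopifnot(length(theta) == 1L)
  parts <- loss_parts(profile, grid, model, spec, hyp)
  lq <- loss_quantiles_at(theta, parts, profile, grid, spec, hyp, model)
  list(extreme_power_loss = lq[1L], extreme_n_gain = lq[2L])
}

## Outcome-indexed, theta-independent pieces of the Phase-III losses.
loss_parts <- function(profile, grid, model, spec, hyp) {
  succ <- profile$reject == 1L & profile$relevant == 1L
  pm <- profile$post_mean
  varhat <- if (model$family == "normal") model$sigma2 else pm * (1 - pm)
  rn <- ifelse(succ, plan_n(pm - hyp$theta0, varhat, spec), 0)
  list(success = succ, realized_n = rn)
}

loss_quantiles_at <- function(theta, parts, profile, grid, spec, hyp,
                              model) {
  mass <- if (grid$family == "binomial") {
    stats::dbinom(profile$node, grid$n, theta)
  } else {
    e <- c(-Inf, (profile$node[-1L] + profile$node[-nrow(profile)]) / 2, Inf)
    diff(stats::pnorm((e - theta) / attr(profile, "sd")))
  }
  vart <- if (model$family == "normal") model$sigma2 else
    theta * (1 - theta)
  rp <- ifelse(parts$success,
               stats::pnorm((theta - hyp$theta0) * sqrt(parts$realized_n) /
                              sqrt(vart) - stats::qnorm(1 - spec$alpha3)),
               0)
  ref_n <- plan_n(theta - hyp$theta0, vart, spec)
  ploss <- spec$target_power - rp
  ngain <- parts$realized_n - ref_n
  c(wquantile(ploss, mass, 1 - spec$zeta),
    wquantile(ngain, mass, 1 - spec$zeta))
}

## Type-1 (left-continuous inverse CDF) weighted quantile.
wquantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p - 1e-12)[1L]]
}
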