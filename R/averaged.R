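#' Sampling prior for the data-generating effect
#'
#' The sampling prior describes uncertainty about the true effect
#' \eqn{\theta} generating the data, as distinct from the analysis prior
#' used to fit them. A point-mass sampling prior recovers frequentist
#' operating characteristics at that effect. An optional truncation interval
#' `(lower, upper]` restricts and renormalizes the distribution, as used for
#' conditional averaging (e.g. monitors averaged over \eqn{\theta >
#' \theta_R}).
#'
#' @param base A [`trial_prior`][priors]: normal, beta or point mass.
#' @param lower,upper Truncation bounds (`-Inf`/`Inf` for none).
#' @return An object of class `sampling_prior`.
#' @examples
#' sampling_prior(normal_prior(0.25, 1 / 50))
#' sampling_prior(normal_prior(0.25, 1 / 50), lower = 0.15)
#' @export
sampling_prior <- function(base, lower = -Inf, upper = Inf) {
  stopifnot(inherits(base, "trial_prior"),
            base$variant %in% c("normal", "beta", "point"), lower < upper)
  mass <- trunc_mass(base, lower, upper)
  if (mass <= 0)
    stop("the truncation interval carries no sampling-prior mass")
  structure(list(base = base, lower = lower, upper = upper, mass = mass),
            class = "sampling_prior")
}

trunc_mass <- function(base, lower, upper) {
  if (base$variant == "point")
    return(as.numeric(base$location > lower && base$location <= upper))
  prior_cdf(base, upper) - prior_cdf(base, lower)
}

#' @export
print.sampling_prior <- function(x, ...) {
  cat("<sampling_prior>", format_prior(x$base))
  if (is.finite(x$lower) || is.finite(x$upper))
    cat(sprintf(" truncated to (%g, %g]", x$lower, x$upper))
  cat("\n")
  invisible(x)
}

## Cached quadrature rules.
.quad_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(order) {
  key <- paste0("gl", order)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussLegendre(order, -1, 1)
  .quad_cache[[key]]
}

gauss_hermite <- function(order) {
  key <- paste0("gh", order)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussHermite(order)
  .quad_cache[[key]]
}

## Nodes x and weights w such that sum(w * f(x)) approximates the average of
## f under the truncated, renormalized sampling prior over (lo, hi].
## Beta bases with a <= 1 have an unbounded density at 0; the substitution
## theta = u^(1/a) removes the singularity.
sp_quad <- function(sp, lo = -Inf, hi = Inf, order = 199L) {
  base <- sp$base
  lo <- max(lo, sp$lower)
  hi <- min(hi, sp$upper)
  if (base$variant == "point") {
    inside <- base$location > lo && base$location <= hi
    if (!inside) return(NULL)
    return(list(x = base$location, w = 1))
  }
  if (base$variant == "normal") {
    qlo <- max(lo, prior_quantile(base, 1e-8))
    qhi <- min(hi, prior_quantile(base, 1 - 1e-8))
  } else {
    qlo <- max(lo, 0)
    qhi <- min(hi, 1)
  }
  if (qlo >= qhi) return(NULL)
  mass <- prior_cdf(base, qhi) - prior_cdf(base, qlo)
  if (mass <= 0) return(NULL)
  gl <- gauss_legendre(order)
  if (base$variant == "beta" && base$a <= 1 && qlo < 1e-3) {
    a <- base$a
    ulo <- qlo^a
    uhi <- qhi^a
    u <- (ulo + uhi) / 2 + (uhi - ulo) / 2 * gl$x
    x <- u^(1 / a)
    jac <- x^(1 - a) / a # d theta / d u
    w <- (uhi - ulo) / 2 * gl$w * prior_density(base, x) * jac
  } else {
    x <- (qlo + qhi) / 2 + (qhi - qlo) / 2 * gl$x
    w <- (qhi - qlo) / 2 * gl$w * prior_density(base, x)
  }
  list(x = x, w = w / mass)
}

#' Average a conditional quantity over the sampling prior
#'
#' Computes \eqn{E^{\pi_s}[f(\theta)]} by Gauss-Legendre quadrature against
#' the (optionally truncated, renormalized) sampling-prior density; a
#' point-mass prior returns `f` at its support point. This is the averaging
#' step that turns frequentist risk into integrated risk.
#'
#' @param f Vectorized function of \eqn{\theta}.
#' @param sp A [sampling_prior()].
#' @param truncation Optional additional interval `c(lo, hi)`.
#' @param order Quadrature order.
#' @return The averaged value.
#' @examples
#' average_over_prior(function(t) t^2, sampling_prior(normal_prior(0, 1)))
#' @export
average_over_prior <- function(f, sp, truncation = NULL, order = 199L) {
  lo <- if (is.null(truncation)) -Inf else truncation[1L]
  hi <- if (is.null(truncation)) Inf else truncation[2L]
  q <- sp_quad(sp, lo, hi, order)
  if (is.null(q))
    stop("the truncation interval carries no sampling-prior mass")
  sum(q$w * f(q$x))
}

#' Sampling-prior operating characteristics at one sample size
#'
#' Builds the outcome grid and rejection profile once, then averages the
#' conditional quantities over the sampling prior: the average type I error
#' rate over the null side \eqn{(-\infty, \theta_0]}, the average type II
#' error rate over the alternative \eqn{(\theta_0, \infty)}, the average MSE
#' over the whole sampling prior, and the indeterminate-outcome probability
#' and extreme Phase-III losses over \eqn{(\theta_R, \infty)}. The weighted
#' sum of average test error rates is
#' \eqn{\mathrm{SATE} = c_1'\bar\alpha + c_0'\bar\beta}.
#'
#' A point-mass sampling prior reduces every quantity to its conditional
#' value at the mass point; the error-rate field on the other side of
#' \eqn{\theta_0} is then `NA` and SATE has a single addend.
#'
#' @inheritParams decide_test
#' @param n Sample size.
#' @param sp A [sampling_prior()].
#' @param p3 A [phase3_spec()].
#' @param control An [oc_control()] list of numerical settings.
#' @return An object of class `averaged_oc`: a list with fields
#'   `avg_type1`, `avg_type2`, `sate`, `amse`, `avg_indeterminate`,
#'   `avg_extreme_power_loss`, `avg_extreme_n_gain`, `n`.
#' @export
averaged_oc <- function(prior, model, n, costs, hyp, sp,
                        p3 = phase3_spec(), control = oc_control()) {
  grid <- build_grid(model, n, sp, hyp, control)
  profile <- rejection_profile(prior, model, n, costs, hyp, grid)
  averaged_oc_from_profile(prior, model, n, costs, hyp, sp, p3, control,
                           grid, profile)
}

averaged_oc_from_profile <- function(prior, model, n, costs, hyp, sp, p3,
                                     control, grid, profile) {
  ord <- control$theta_nodes
  if (sp$base$variant == "point") {
    t0 <- sp$base$location
    pr <- p_reject(t0, profile, grid)
    a1 <- if (t0 <= hyp$theta0) pr else NA_real_
    a2 <- if (t0 > hyp$theta0) 1 - pr else NA_real_
    amse <- cond_mse(t0, prior, model, n, grid, profile,
                     control$gh_order)
    ind <- cond_indeterminate(t0, profile, grid)
    parts <- loss_parts(profile, grid, model, p3, hyp)
    lq <- loss_quantiles_at(t0, parts, profile, grid, p3, hyp, model)
    sate <- sum(c(costs$c1p * a1, costs$c0p * a2), na.rm = TRUE)
    return(new_averaged_oc(n, a1, a2, sate, amse, ind, lq[1L], lq[2L]))
  }
  q_null <- sp_quad(sp, hi = hyp$theta0, order = ord)
  q_alt <- sp_quad(sp, lo = hyp$theta0, order = ord)
  q_all <- sp_quad(sp, order = ord)
  q_rel <- sp_quad(sp, lo = hyp$thetaR, order = ord)
  a1 <- if (is.null(q_null)) NA_real_ else
    sum(q_null$w * p_reject(q_null$x, profile, grid))
  a2 <- if (is.null(q_alt)) NA_real_ else
    sum(q_alt$w * (1 - p_reject(q_alt$x, profile, grid)))
  amse <- sum(q_all$w * cond_mse(q_all$x, prior, model, n, grid, profile,
                                 control$gh_order))
  if (is.null(q_rel)) {
    ind <- epl <- eng <- NA_real_
  } else {
    ind <- sum(q_rel$w * cond_indeterminate(q_rel$x, profile, grid))
    parts <- loss_parts(profile, grid, model, p3, hyp)
    lq <- vapply(q_rel$x, loss_quantiles_at, numeric(2L), parts = parts,
                 profile = profile, grid = grid, spec = p3, hyp = hyp,
                 model = model)
    epl <- sum(q_rel$w * lq[1L, ])
    eng <- sum(q_rel$w * lq[2L, ])
  }
  sate <- sum(c(costs$c1p * a1, costs$c0p * a2), na.rm = TRUE)
  new_averaged_oc(n, a1, a2, sate, amse, ind, epl, eng)
}

new_averaged_oc <- function(n, a1, a2, sate, amse, ind, epl, eng) {
  structure(list(n = n, avg_type1 = a1, avg_type2 = a2, sate = sate,
                 amse = amse, avg_indeterminate = ind,
                 avg_extreme_power_loss = epl, avg_extreme_n_gain = eng),
            class = "averaged_oc")
}

#' @export
print.averaged_oc <- function(x, ...) {
  cat(sprintf(
    paste0("<averaged_oc> n = %d: alpha-bar = %.4g, beta-bar = %.4g, ",
           "SATE = %.4g, AMSE = %.4g\n  P(indeterminate) = %.4g, ",
           "extreme power loss = %.4g, extreme n gain = %.4g\n"),
    x$n, x$avg_type1, x$avg_type2, x$sate, x$amse, x$avg_indeterminate,
    x$avg_extreme_power_loss, x$avg_extreme_n_gain))
  invisible(x)
}

#' Numerical settings for operating-characteristic computations
#'
#' @param theta_nodes Gauss-Legendre order for sampling-prior averaging.
#' @param outcome_nodes Grid size over \eqn{\bar{y}} (normal family).
#' @param gh_order Gauss-Hermite order for conditional MSE (normal family).
#' @param pad Outcome-grid extension in outcome standard deviations.
#' @return A list of settings.
#' @export
oc_control <- function(theta_nodes = 199L, outcome_nodes = 801L,
                       gh_order = 199L, pad = 9) {
  list(theta_nodes = as.integer(theta_nodes),
       outcome_nodes = as.integer(outcome_nodes),
       gh_order = as.integer(gh_order), pad = pad)
}

build_grid <- function(model, n, sp, hyp, control) {
  if (model$family == "binomial") return(outcome_grid(model, n))
  if (sp$base$variant == "point") {
    tr <- sp$base$location + c(-1, 1) * 0.5 * sqrt(model$sigma2)
  } else {
    tr <- prior_quantile(sp$base, c(1e-8, 1 - 1e-8))
  }
  tr <- range(c(tr, hyp$theta0, hyp$thetaR))
  outcome_grid(model, n, theta_range = tr, nodes = control$outcome_nodes,
               pad = control$pad)
}

#' Integrated-risk costs implied by the sampling prior
#'
#' The working costs entering the integrated risk are the user costs
#' inflated by the inverse sampling-prior hypothesis masses:
#' \eqn{c_0 = c_0'/P^{\pi_s}(\theta > \theta_0)} and
#' \eqn{c_1 = c_1'/P^{\pi_s}(\theta \le \theta_0)}.
#'
#' @param costs A [cost_spec()].
#' @param sp A [sampling_prior()].
#' @param hyp A [hypotheses()].
#' @return `list(c0, c1)`.
#' @export
sampling_prior_costs <- function(costs, sp, hyp) {
  p0 <- (trunc_mass(sp$base, sp$lower, min(sp$upper, hyp$theta0))) / sp$mass
  if (p0 <= 0 || p0 >= 1)
    stop("the sampling prior puts no mass on one side of theta0; use a ",
         "point-mass sampling prior for frequentist operating characteristics")
  list(c0 = costs$c0p / (1 - p0), c1 = costs$c1p / p0)
}
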