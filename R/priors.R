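#' Analysis prior constructors
#'
#' Analysis priors drive posterior inference and trial decisions. Conjugate
#' single-component families (normal, beta), degenerate point masses, finite
#' mixtures, and power priors built from historical data are supported.
#'
#' The power prior raises the historical likelihood to a power
#' \eqn{a_0 \in [0, 1]} before combining it with a baseline prior, so that
#' `a0 = 1` recovers the posterior given the full historical data and
#' `a0 = 0` recovers the baseline. `a0 = "empirical_bayes"` selects the
#' discounting weight per dataset by marginal-likelihood maximization (see
#' [eb_a0()]), making the prior data-dependent.
#'
#' @param mean,var Mean and variance of a normal prior (`var > 0`).
#' @param a,b Shape parameters of a beta prior (both `> 0`).
#' @param location Support point of a degenerate prior.
#' @param components List of priors to mix; all of the same family.
#' @param weights Mixture weights: nonnegative, summing to 1.
#' @param historical A [historical_data()] summary.
#' @param baseline Prior to which the discounted historical likelihood is
#'   applied (e.g. a vague normal, or `beta_prior(1, 1)`).
#' @param a0 Fixed discounting weight in `[0, 1]`, or `"empirical_bayes"`.
#' @return An object of class `trial_prior` (subclassed by variant).
#' @examples
#' normal_prior(0, 100)
#' beta_prior(0.0811, 1)
#' mixture_prior(list(beta_prior(11, 29), beta_prior(1, 1)), c(0.5, 0.5))
#' power_prior(historical_data(38, successes = 10, failures = 28),
#'             beta_prior(1, 1), a0 = 1)
#' @name priors
NULL

new_prior <- function(variant, fields) {
  structure(c(list(variant = variant), fields),
            class = c(paste0(variant, "_prior"), "trial_prior"))
}

#' @rdname priors
#' @export
normal_prior <- function(mean, var) {
  stopifnot(is.numeric(mean), is.numeric(var), var > 0)
  new_prior("normal", list(mean = mean, var = var))
}

#' @rdname priors
#' @export
beta_prior <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  new_prior("beta", list(a = a, b = b))
}

#' @rdname priors
#' @export
point_prior <- function(location) {
  stopifnot(is.numeric(location), length(location) == 1L)
  new_prior("point", list(location = location))
}

#' @rdname priors
#' @export
mixture_prior <- function(components, weights) {
  stopifnot(is.list(components), length(components) == length(weights),
            all(vapply(components, inherits, TRUE, "trial_prior")))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("mixture weights must be nonnegative and sum to 1")
  # degenerate weights collapse to the surviving component
  keep <- weights > 0
  if (sum(keep) == 1L) return(components[[which(keep)]])
  new_prior("mixture", list(components = components[keep],
                            weights = weights[keep] / sum(weights[keep])))
}

#' @rdname priors
#' @export
power_prior <- function(historical, baseline, a0 = "empirical_bayes") {
  stopifnot(inherits(historical, "historical_data"),
            inherits(baseline, "trial_prior"))
  if (is.character(a0)) {
    a0 <- match.arg(a0, "empirical_bayes")
  } else {
    stopifnot(is.numeric(a0), length(a0) == 1L, a0 >= 0, a0 <= 1)
  }
  new_prior("power", list(historical = historical, baseline = baseline,
                          a0 = a0))
}

#' @export
print.trial_prior <- function(x, ...) {
  cat("<trial_prior>", format_prior(x), "\n")
  invisible(x)
}

format_prior <- function(p) {
  switch(p$variant,
    normal  = sprintf("N(%g, %g)", p$mean, p$var),
    beta    = sprintf("Beta(%g, %g)", p$a, p$b),
    point   = sprintf("point mass at %g", p$location),
    mixture = paste(sprintf("%.3g*%s", p$weights,
                            vapply(p$components, format_prior, "")),
                    collapse = " + "),
    power   = sprintf("power prior (a0 = %s) on %s",
                      if (is.character(p$a0)) "EB" else format(p$a0),
                      format_prior(p$baseline)))
}

is_data_dependent <- function(prior) {
  switch(prior$variant,
    power   = is.character(prior$a0),
    mixture = any(vapply(prior$components, is_data_dependent, TRUE)),
    FALSE)
}

## Resolve a (possibly data-dependent) prior to concrete conjugate form.
## Power priors collapse to their induced normal/beta prior; with the
## empirical-Bayes flag, a0 is chosen from the current data first.
resolve_prior <- function(prior, model = NULL, data = NULL) {
  switch(prior$variant,
    power = {
      a0 <- prior$a0
      if (is.character(a0)) {
        if (is.null(data) || data$n < 1)
          stop("empirical-Bayes power prior needs current data (n >= 1) ",
               "to select a0; the marginal likelihood is undefined otherwise")
        a0 <- eb_a0(prior$historical, prior$baseline, model, data)
      }
      out <- apply_power(prior$historical, prior$baseline, a0, model)
      attr(out, "a0") <- a0
      out
    },
    mixture = {
      comps <- lapply(prior$components, resolve_prior, model = model,
                      data = data)
      mixture_prior(comps, prior$weights)
    },
    prior)
}

## Concrete prior induced by discounting the historical likelihood by a0.
apply_power <- function(historical, baseline, a0, model) {
  if (historical$family == "normal") {
    if (baseline$variant != "normal")
      stop("normal historical data requires a normal baseline prior")
    s2 <- if (!is.null(model$sigma2)) model$sigma2 else 1
    prec <- 1 / baseline$var + a0 * historical$n0 / s2
    mu <- (baseline$mean / baseline$var +
             a0 * historical$n0 * historical$mean / s2) / prec
    normal_prior(mu, 1 / prec)
  } else {
    if (baseline$variant != "beta")
      stop("binomial historical data requires a beta baseline prior")
    beta_prior(baseline$a + a0 * historical$successes,
               baseline$b + a0 * historical$failures)
  }
}

## Prior CDF; mixtures are weight-averaged, with log-scale accumulation
## when log.p = TRUE so that extreme tails keep relative accuracy.
prior_cdf <- function(prior, q, lower.tail = TRUE, log.p = FALSE) {
  switch(prior$variant,
    normal = stats::pnorm(q, prior$mean, sqrt(prior$var),
                          lower.tail = lower.tail, log.p = log.p),
    beta   = stats::pbeta(q, prior$a, prior$b,
                          lower.tail = lower.tail, log.p = log.p),
    point  = {
      p <- as.numeric(if (lower.tail) prior$location <= q else prior$location > q)
      if (log.p) log(p) else p
    },
    mixture = {
      lp <- vapply(prior$components, prior_cdf, numeric(length(q)),
                   q = q, lower.tail = lower.tail, log.p = TRUE)
      lp <- matrix(lp, nrow = length(q))
      out <- apply(lp, 1L, function(r) logsumexp(r + log(prior$weights)))
      if (log.p) out else exp(out)
    },
    power = stop("resolve the power prior before evaluating its CDF"))
}

prior_mean_value <- function(prior) {
  switch(prior$variant,
    normal  = prior$mean,
    beta    = prior$a / (prior$a + prior$b),
    point   = prior$location,
    mixture = sum(prior$weights *
                    vapply(prior$components, prior_mean_value, 0)),
    power   = stop("resolve the power prior before taking its mean"))
}

prior_quantile <- function(prior, p) {
  switch(prior$variant,
    normal  = stats::qnorm(p, prior$mean, sqrt(prior$var)),
    beta    = stats::qbeta(p, prior$a, prior$b),
    point   = rep(prior$location, length(p)),
    mixture = {
      # bracketed numerical inversion of the mixture CDF
      rng <- range(vapply(prior$components, prior_quantile, numeric(2L),
                          p = c(min(p), max(p))))
      vapply(p, function(pp) {
        stats::uniroot(function(x) prior_cdf(prior, x) - pp,
                       lower = rng[1] - 1e-9, upper = rng[2] + 1e-9,
                       extendInt = "upX", tol = 1e-10)$root
      }, 0)
    },
    power   = stop("resolve the power prior before taking quantiles"))
}

prior_density <- function(prior, x) {
  switch(prior$variant,
    normal  = stats::dnorm(x, prior$mean, sqrt(prior$var)),
    beta    = stats::dbeta(x, prior$a, prior$b),
    mixture = {
      d <- vapply(prior$components, prior_density, numeric(length(x)), x = x)
      as.numeric(matrix(d, nrow = length(x)) %*% prior$weights)
    },
    stop("density undefined for variant '", prior$variant, "'"))
}

#' Prior probability mass below a threshold
#'
#' Evaluates \eqn{P^{\pi}(\theta \le t)} for a proper analysis prior.
#' Mixtures are weight-averaged. Power priors with fixed `a0` are resolved
#' first; the empirical-Bayes variant needs data and is rejected here.
#'
#' @param prior A [`trial_prior`][priors].
#' @param t Threshold.
#' @param model A [trial_model()] (needed to resolve fixed-`a0` power priors).
#' @return Probability in `[0, 1]`.
#' @examples
#' prior_mass_below(beta_prior(0.0811, 1), 0.075) # = 0.075^0.0811
#' @export
prior_mass_below <- function(prior, t, model = NULL) {
  if (prior$variant == "power") {
    if (is.character(prior$a0))
      stop("the empirical-Bayes power prior is data-dependent; ",
           "use posterior/decision functions that receive the data")
    prior <- resolve_prior(prior, model)
  }
  prior_cdf(prior, t)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
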