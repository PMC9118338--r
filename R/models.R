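#' Outcome model for a single-arm trial
#'
#' Two conjugate families are supported: a normal outcome with known variance,
#' where all computations act on the sufficient statistic
#' \eqn{\bar{y} \sim N(\theta, \sigma^2/n)}, and a binomial outcome with
#' success count \eqn{y \sim Bin(n, \theta)}.
#'
#' @param family `"normal"` (known variance) or `"binomial"`.
#' @param sigma2 Outcome variance \eqn{\sigma^2} (normal family only).
#' @return An object of class `trial_model`.
#' @examples
#' trial_model("normal", sigma2 = 1)
#' trial_model("binomial")
#' @export
trial_model <- function(family = c("normal", "binomial"), sigma2 = NULL) {
  family <- match.arg(family)
  if (family == "normal") {
    if (is.null(sigma2)) sigma2 <- 1
    stopifnot(is.numeric(sigma2), length(sigma2) == 1L, sigma2 > 0)
  } else {
    if (!is.null(sigma2)) stop("'sigma2' applies only to the normal family")
  }
  structure(list(family = family, sigma2 = sigma2), class = "trial_model")
}

#' Observed trial data as a sufficient statistic
#'
#' @param n Sample size (positive integer). `n = 0` is allowed and stands for
#'   "no data": posteriors then equal the prior.
#' @param stat Sample mean \eqn{\bar{y}} (normal family) or integer success
#'   count \eqn{y \in \{0, \dots, n\}} (binomial family).
#' @return An object of class `trial_data`.
#' @examples
#' trial_data(25, 5)
#' trial_data(100, 0.3)
#' @export
trial_data <- function(n, stat = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  if (n == 0) stat <- NA_real_
  stopifnot(n == 0 || (is.numeric(stat) && length(stat) == 1L))
  structure(list(n = as.integer(n), stat = as.numeric(stat)),
            class = "trial_data")
}

#' Historical study summary used to build power priors
#'
#' @param n0 Historical sample size.
#' @param mean Historical sample mean \eqn{\bar{y}_0} (normal family).
#' @param successes,failures Historical outcome counts (binomial family);
#'   they must sum to `n0`.
#' @return An object of class `historical_data`.
#' @examples
#' historical_data(50, mean = 0.25)
#' historical_data(38, successes = 10, failures = 28)
#' @export
historical_data <- function(n0, mean = NULL, successes = NULL, failures = NULL) {
  stopifnot(is.numeric(n0), length(n0) == 1L, n0 >= 1, n0 == round(n0))
  if (!is.null(mean)) {
    if (!is.null(successes) || !is.null(failures))
      stop("give either 'mean' (normal) or 'successes'/'failures' (binomial)")
    out <- list(n0 = as.integer(n0), mean = as.numeric(mean),
                family = "normal")
  } else {
    stopifnot(is.numeric(successes), is.numeric(failures))
    if (successes + failures != n0)
      stop("'successes' + 'failures' must equal 'n0'")
    out <- list(n0 = as.integer(n0), successes = as.numeric(successes),
                failures = as.numeric(failures), family = "binomial")
  }
  structure(out, class = "historical_data")
}

check_data <- function(model, data) {
  stopifnot(inherits(model, "trial_model"), inherits(data, "trial_data"))
  if (data$n > 0 && model$family == "binomial") {
    if (data$stat < 0 || data$stat > data$n || data$stat != round(data$stat))
      stop("binomial 'stat' must be an integer success count in 0..n")
  }
  invisible(TRUE)
}

#' @export
print.trial_model <- function(x, ...) {
  if (x$family == "normal")
    cat(sprintf("<trial_model> normal outcome, known variance sigma^2 = %g\n",
                x$sigma2))
  else cat("<trial_model> binomial outcome\n")
  invisible(x)
}
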