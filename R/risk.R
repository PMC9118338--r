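#' Operating-characteristic curve over a sample-size grid
#'
#' One [averaged_oc()] evaluation per sample size. The returned curve stores
#' the average error rates and monitors alongside SATE and AMSE so that
#' goal-sampling targets can be read off without recomputation; the `risk`
#' column stays `NA` until costs are supplied to [integrated_risk()].
#'
#' @inheritParams averaged_oc
#' @param n_grid Increasing vector of integer sample sizes.
#' @return A `risk_curve`: a data frame with one row per `n` and columns
#'   `n`, `avg_type1`, `avg_type2`, `sate`, `amse`, `avg_indeterminate`,
#'   `avg_extreme_power_loss`, `avg_extreme_n_gain`, `risk`.
#' @export
oc_curve <- function(prior, model, costs, hyp, sp, p3 = phase3_spec(),
                     n_grid, control = oc_control()) {
  stopifnot(length(n_grid) >= 1L, !is.unsorted(n_grid, strictly = TRUE),
            all(n_grid >= 1))
  rows <- lapply(n_grid, function(n) {
    oc <- averaged_oc(prior, model, n, costs, hyp, sp, p3, control)
    as.data.frame(unclass(oc))
  })
  out <- do.call(rbind, rows)
  out$risk <- NA_real_
  class(out) <- c("risk_curve", "data.frame")
  attr(out, "costs") <- costs
  out
}

#' Local polynomial smoothing of a per-n curve
#'
#' Weighted local quadratic least squares: at each grid point the
#' `bandwidth` nearest points are fitted with a degree-2 polynomial under
#' tricube weights (set `kernel = "uniform"` for plain least squares) and
#' the fit is evaluated at that point. Windows truncate one-sidedly at the
#' grid ends. Exactly polynomial input of degree at most 2 is reproduced
#' unchanged. Discrete-outcome designs make SATE(n) a sawtooth in `n`; a
#' window spanning a sizeable fraction of the grid is needed to recover its
#' trend (see [elicit_costs()]).
#'
#' @param values Curve values, one per grid point.
#' @param n_grid The sample-size grid.
#' @param bandwidth Window size in grid points (at least 3; clamped with a
#'   warning when it exceeds the grid length).
#' @param degree Polynomial degree of the local fit.
#' @param kernel `"tricube"` or `"uniform"` window weights.
#' @return Smoothed values on the same grid.
#' @export
smooth_curve <- function(values, n_grid, bandwidth, degree = 2L,
                         kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  m <- length(n_grid)
  stopifnot(length(values) == m)
  if (bandwidth < 3L) stop("'bandwidth' must span at least 3 grid points")
  if (bandwidth > m) {
    warning("'bandwidth' exceeds the grid length; clamped to ", m)
    bandwidth <- m
  }
  vapply(seq_len(m), function(i) {
    local_poly_fit(values, n_grid, n_grid[i], bandwidth, degree, kernel,
                   deriv = FALSE)
  }, 0)
}

## Local polynomial fit at x0 using the k nearest grid points; returns the
## fitted value or the first derivative of the local polynomial.
local_poly_fit <- function(values, n_grid, x0, k, degree, kernel, deriv) {
  d <- abs(n_grid - x0)
  idx <- order(d)[seq_len(min(k, length(n_grid)))]
  w <- if (kernel == "tricube") {
    dm <- max(d[idx])
    if (dm == 0) rep(1, length(idx)) else (1 - pmin(1, d[idx] / dm)^3)^3
  } else rep(1, length(idx))
  keep <- w > 0
  idx <- idx[keep]
  w <- w[keep]
  X <- outer(n_grid[idx] - x0, 0:degree, "^")
  fit <- stats::lm.wfit(X, values[idx], w)
  if (deriv) unname(fit$coefficients[2L]) else unname(fit$coefficients[1L])
}

#' Implied per-observation cost from a curve derivative
#'
#' The goal-sampling connection: if a sample size `n_star` was accepted to
#' reach a target on this curve, the implied cost per observation is the
#' negative slope of the curve there, \eqn{c_n = -dV(n)/dn |_{n^*}}. The
#' slope is a central finite difference over adjacent grid points (one-sided
#' at the ends), optionally after [smooth_curve()] smoothing.
#'
#' @param values Curve values (e.g. SATE or AMSE per `n`).
#' @param n_grid The sample-size grid.
#' @param n_star The elicited sample size (must lie on the grid).
#' @param smooth Smooth the curve before differencing?
#' @param bandwidth Window for [smooth_curve()]; default 75\% of the grid.
#' @return A positive cost per observation.
#' @export
unit_cost <- function(values, n_grid, n_star, smooth = FALSE,
                      bandwidth = NULL) {
  i <- match(n_star, n_grid)
  if (is.na(i)) stop("'n_star' is not a point of 'n_grid'")
  if (smooth) {
    if (is.null(bandwidth)) bandwidth <- ceiling(0.75 * length(n_grid))
    values <- smooth_curve(values, n_grid, bandwidth)
  }
  lo <- max(1L, i - 1L)
  hi <- min(length(n_grid), i + 1L)
  slope <- (values[hi] - values[lo]) / (n_grid[hi] - n_grid[lo])
  cost <- -slope
  if (cost <= 0)
    stop("the curve is locally non-decreasing at n_star (cost ", cost,
         "); for sawtooth curves retry with smooth = TRUE")
  cost
}

#' Elicit integrated-risk costs from goal-sampling targets
#'
#' Given the sample sizes `n_sate` and `n_amse` accepted to reach the
#' testing and estimation targets, infers the per-observation costs from the
#' curve slopes ([unit_cost()]), sets the testing weight
#' \eqn{w = n^{SATE}/(n^{SATE} + n^{AMSE})} (the importance of each target
#' taken proportional to the patients one would pay for it), and recovers
#' the raw risk coefficients \eqn{c_q = (1-w)c_n^{SATE}/(w\, c_n^{AMSE})}
#' and \eqn{c_n = c_n^{SATE}/w}.
#'
#' @param n_sate,n_amse Elicited sample sizes for the testing and
#'   estimation targets.
#' @param sate_curve,amse_curve Curve values per grid point.
#' @param n_grid The sample-size grid both curves were computed on.
#' @param smooth_sate,smooth_amse Smooth before differencing? Discrete
#'   (binomial) SATE curves need it; smooth curves do not.
#' @param bandwidth Window passed to [smooth_curve()].
#' @param w Override the auto-derived weight.
#' @return A `cost_elicitation`: list with `n_sate`, `n_amse`, `cn_sate`,
#'   `cn_amse`, `w`, `cq`, `cn`.
#' @export
elicit_costs <- function(n_sate, n_amse, sate_curve, amse_curve, n_grid,
                         smooth_sate = FALSE, smooth_amse = FALSE,
                         bandwidth = NULL, w = NULL) {
  cn_sate <- unit_cost(sate_curve, n_grid, n_sate, smooth_sate, bandwidth)
  cn_amse <- unit_cost(amse_curve, n_grid, n_amse, smooth_amse, bandwidth)
  auto_w <- is.null(w)
  if (auto_w) w <- n_sate / (n_sate + n_amse)
  structure(list(n_sate = n_sate, n_amse = n_amse, cn_sate = cn_sate,
                 cn_amse = cn_amse, w = w,
                 cq = ((1 - w) * cn_sate) / (w * cn_amse),
                 cn = cn_sate / w, auto_w = auto_w),
            class = "cost_elicitation")
}

#' @export
print.cost_elicitation <- function(x, ...) {
  cat(sprintf(
    paste0("<cost_elicitation> n_SATE = %d, n_AMSE = %d\n",
           "  cn_SATE = %.4g, cn_AMSE = %.4g, w = %.3f, cq = %.4g, ",
           "cn = %.4g\n"),
    x$n_sate, x$n_amse, x$cn_sate, x$cn_amse, x$w, x$cq, x$cn))
  invisible(x)
}

#' Fill the integrated risk column of an OC curve
#'
#' The rescaled combined risk
#' \deqn{r(n) = \frac{w}{c_n^{SATE}} \mathrm{SATE}(n) +
#'   \frac{1-w}{c_n^{AMSE}} \mathrm{AMSE}(n) + n,}
#' whose minimizer is invariant to the rescaling. With `raw = TRUE` the
#' unscaled parameterization \eqn{\mathrm{SATE}(n) + c_q \mathrm{AMSE}(n) +
#' c_n n} is used instead (identical minimizer; useful when actual monetary
#' costs are supplied).
#'
#' @param curve A `risk_curve` from [oc_curve()].
#' @param costs A `cost_elicitation` from [elicit_costs()].
#' @param raw Use the raw \eqn{(c_q, c_n)} parameterization.
#' @return The curve with its `risk` column filled.
#' @export
integrated_risk <- function(curve, costs, raw = FALSE) {
  stopifnot(inherits(curve, "risk_curve"), inherits(costs, "cost_elicitation"))
  curve$risk <- if (raw) {
    curve$sate + costs$cq * curve$amse + costs$cn * curve$n
  } else {
    (costs$w / costs$cn_sate) * curve$sate +
      ((1 - costs$w) / costs$cn_amse) * curve$amse + curve$n
  }
  attr(curve, "elicitation") <- costs
  curve
}

#' Risk-minimizing sample size
#'
#' Argmin of the filled risk column over the integer grid; ties break toward
#' the smallest `n`. A minimum on the upper grid boundary triggers a warning
#' since the true optimum may be truncated away.
#'
#' @param curve A `risk_curve` with `risk` filled.
#' @return A `design_result`: list with `n_opt`, `risk_at_opt`,
#'   `oc_at_opt` (the curve row at the optimum).
#' @export
optimal_n <- function(curve) {
  stopifnot(inherits(curve, "risk_curve"), !all(is.na(curve$risk)))
  i <- which.min(curve$risk)
  if (i == nrow(curve))
    warning("risk minimized at the upper end of the sample-size grid; ",
            "the optimum may lie beyond it")
  structure(list(n_opt = curve$n[i], risk_at_opt = curve$risk[i],
                 oc_at_opt = curve[i, ]),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("<design_result> n_opt = %d, risk = %.6g\n", x$n_opt,
              x$risk_at_opt))
  invisible(x)
}

#' Goal-sampling sample sizes from OC targets
#'
#' The smallest sample size whose testing (respectively estimation) targets
#' hold *at that n and every larger grid n*. The suffix rule guards against
#' the non-monotone, sawtooth OC declines of discrete outcome models, where
#' a target met at some n can fail again slightly above it. Targets are
#' named upper bounds on curve columns, e.g. `list(avg_type2 = 0.2)` or
#' `list(amse = 0.006, avg_indeterminate = 0.1)`.
#'
#' @param curve A `risk_curve`.
#' @param sate_targets,amse_targets Named lists of upper bounds for the
#'   testing and estimation goals.
#' @return List with `n_sate`, `n_amse`, and `n_goal = max` of the two (the
#'   strict goal-sampling choice).
#' @export
goal_n <- function(curve, sate_targets = NULL, amse_targets = NULL) {
  stopifnot(inherits(curve, "risk_curve"))
  first_suffix <- function(targets) {
    if (is.null(targets) || length(targets) == 0L) return(NA_integer_)
    ok <- rep(TRUE, nrow(curve))
    for (nm in names(targets)) {
      if (!nm %in% names(curve)) stop("unknown target column '", nm, "'")
      ok <- ok & (curve[[nm]] <= targets[[nm]])
    }
    ok[is.na(ok)] <- FALSE
    suffix <- rev(cumprod(rev(ok))) > 0 # holds here and at all larger n
    if (!any(suffix)) {
      best <- vapply(names(targets), function(nm)
        min(curve[[nm]], na.rm = TRUE), 0)
      stop("targets unachievable on the grid; best values reached: ",
           paste(sprintf("%s = %.4g", names(targets), best),
                 collapse = ", "))
    }
    curve$n[which(suffix)[1L]]
  }
  ns <- first_suffix(sate_targets)
  na <- first_suffix(amse_targets)
  list(n_sate = ns, n_amse = na, n_goal = max(ns, na, na.rm = TRUE))
}

#' Sensitivity of design and operating characteristics to the sampling prior
#'
#' Re-evaluates the design over a grid of sampling priors (the candidate
#' data-generating mechanisms) for each analysis prior, retaining one shared
#' cost elicitation so the integrated risks stay comparable. With `fixed_n`
#' the sample size is held fixed and no optimization is run; otherwise the
#' risk is minimized over `n_grid` for every cell.
#'
#' @param analysis_priors Named list of analysis priors.
#' @param sp_grid List of [sampling_prior()]s (optionally named).
#' @param model,costs,hyp,p3,control As in [averaged_oc()].
#' @param elicitation A `cost_elicitation` shared across the scan.
#' @param n_grid Sample-size grid for per-cell optimization.
#' @param fixed_n Fixed sample size (skips optimization).
#' @return A `sensitivity_table` data frame: one row per (sampling prior,
#'   analysis prior) with the sampling-prior mean, selected `n`, risk,
#'   average error rates, AMSE, and the sampling-prior working costs
#'   `c0`, `c1`. Failed cells yield `NA` values and a message.
#' @export
sensitivity_scan <- function(analysis_priors, sp_grid, model, costs,
                             elicitation, hyp, p3 = phase3_spec(),
                             n_grid = NULL, fixed_n = NULL,
                             control = oc_control()) {
  stopifnot(is.list(analysis_priors), length(names(analysis_priors)) > 0,
            is.list(sp_grid))
  if (is.null(fixed_n) && is.null(n_grid))
    stop("give either 'n_grid' (optimize n per cell) or 'fixed_n'")
  sp_names <- names(sp_grid)
  if (is.null(sp_names)) sp_names <- as.character(seq_along(sp_grid))
  rows <- list()
  for (j in seq_along(sp_grid)) {
    sp <- sp_grid[[j]]
    sp_mean <- prior_mean_value(sp$base)
    wc <- tryCatch(sampling_prior_costs(costs, sp, hyp),
                   error = function(e) list(c0 = NA_real_, c1 = NA_real_))
    for (nm in names(analysis_priors)) {
      cell <- tryCatch({
        if (is.null(fixed_n)) {
          cv <- oc_curve(analysis_priors[[nm]], model, costs, hyp, sp, p3,
                         n_grid, control)
          cv <- integrated_risk(cv, elicitation)
          opt <- suppressWarnings(optimal_n(cv))
          cbind(n = opt$n_opt, risk = opt$risk_at_opt,
                opt$oc_at_opt[c("avg_type1", "avg_type2", "amse")])
        } else {
          oc <- averaged_oc(analysis_priors[[nm]], model, fixed_n, costs,
                            hyp, sp, p3, control)
          risk <- (elicitation$w / elicitation$cn_sate) * oc$sate +
            ((1 - elicitation$w) / elicitation$cn_amse) * oc$amse + fixed_n
          data.frame(n = fixed_n, risk = risk, avg_type1 = oc$avg_type1,
                     avg_type2 = oc$avg_type2, amse = oc$amse)
        }
      }, error = function(e) {
        message("sensitivity cell (", sp_names[j], ", ", nm, ") failed: ",
                conditionMessage(e))
        data.frame(n = NA_integer_, risk = NA_real_, avg_type1 = NA_real_,
                   avg_type2 = NA_real_, amse = NA_real_)
      })
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(sampling = sp_names[j], sp_mean = sp_mean,
                         analysis_prior = nm), cell,
              data.frame(c0 = wc$c0, c1 = wc$c1))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}
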