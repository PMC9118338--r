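## Scenario configuration: strict YAML schema -> package objects.

schema_keys <- list(
  top = c("model", "hypotheses", "analysis_priors", "sampling", "costs",
          "phase3", "elicitation", "numerics", "output"),
  model = c("family", "sigma2"),
  hypotheses = c("theta0", "thetaR"),
  costs = c("c0p", "c1p", "mode", "normalize"),
  phase3 = c("target_power", "alpha3", "zeta", "n_cap"),
  sampling = c("type", "mean", "var", "a", "b", "location", "lower",
               "upper", "grid"),
  elicitation = c("analysis_prior", "n_sate", "n_amse", "smooth_sate",
                  "smooth_amse", "bandwidth", "elicit_grid", "sate_targets",
                  "amse_targets"),
  numerics = c("theta_nodes", "outcome_nodes", "gh_order", "n_grid",
               "eval_n", "seed"),
  output = c("dir", "formats"))

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0)
    stop("unknown key(s) in '", where, "': ", paste(extra, collapse = ", "))
}

parse_prior <- function(spec, where = "prior") {
  if (!is.list(spec) || is.null(spec$type))
    stop("'", where, "' must be a mapping with a 'type' key")
  switch(spec$type,
    normal = {
      check_keys(spec, c("type", "mean", "var"), where)
      normal_prior(spec$mean, spec$var)
    },
    beta = {
      check_keys(spec, c("type", "a", "b"), where)
      beta_prior(spec$a, spec$b)
    },
    point = {
      check_keys(spec, c("type", "location"), where)
      point_prior(spec$location)
    },
    mixture = {
      check_keys(spec, c("type", "components", "weights"), where)
      mixture_prior(lapply(seq_along(spec$components), function(i)
        parse_prior(spec$components[[i]],
                    paste0(where, ".components[", i, "]"))),
        as.numeric(spec$weights))
    },
    power = {
      check_keys(spec, c("type", "a0", "baseline", "historical"), where)
      h <- spec$historical
      check_keys(h, c("n0", "mean", "successes", "failures"),
                 paste0(where, ".historical"))
      hist <- if (!is.null(h$mean)) {
        historical_data(h$n0, mean = h$mean)
      } else {
        historical_data(h$n0, successes = h$successes,
                        failures = h$failures)
      }
      power_prior(hist, parse_prior(spec$baseline,
                                    paste0(where, ".baseline")), spec$a0)
    },
    stop("unknown prior type '", spec$type, "' in '", where, "'"))
}

parse_ngrid <- function(g, where) {
  check_keys(g, c("from", "to", "by"), where)
  seq(g$from, g$to, by = if (is.null(g$by)) 1L else g$by)
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file describing the outcome model, hypothesis
#' thresholds, named analysis priors, sampling prior, costs, Phase-III
#' settings, cost-elicitation inputs, and numerical settings. Unknown keys
#' anywhere in the file are rejected. Two complete scenarios ship with the
#' package (see [trialrisk_scenarios()]).
#'
#' @param path Path to a YAML file.
#' @return A `scenario` object: a validated list of package objects.
#' @examples
#' sc <- load_scenario(trialrisk_scenarios("binomial_poc"))
#' sc$hyp
#' @export
load_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0) stop("empty scenario file: ", path)
  check_keys(cfg, schema_keys$top, "scenario")
  for (req in c("model", "hypotheses", "analysis_priors", "sampling",
                "costs"))
    if (is.null(cfg[[req]])) stop("missing required block '", req, "'")
  check_keys(cfg$model, schema_keys$model, "model")
  model <- trial_model(cfg$model$family, cfg$model$sigma2)
  check_keys(cfg$hypotheses, schema_keys$hypotheses, "hypotheses")
  hyp <- if (is.null(cfg$hypotheses$thetaR)) {
    hypotheses(cfg$hypotheses$theta0)
  } else {
    hypotheses(cfg$hypotheses$theta0, cfg$hypotheses$thetaR)
  }
  priors <- lapply(names(cfg$analysis_priors), function(nm)
    parse_prior(cfg$analysis_priors[[nm]],
                paste0("analysis_priors.", nm)))
  names(priors) <- names(cfg$analysis_priors)
  check_keys(cfg$sampling, schema_keys$sampling, "sampling")
  s <- cfg$sampling
  sp <- sampling_prior(parse_prior(s[setdiff(names(s),
                                             c("lower", "upper", "grid"))],
                                   "sampling"),
                       lower = if (is.null(s$lower)) -Inf else s$lower,
                       upper = if (is.null(s$upper)) Inf else s$upper)
  check_keys(cfg$costs, schema_keys$costs, "costs")
  costs <- cost_spec(cfg$costs$c0p, cfg$costs$c1p,
                     mode = if (is.null(cfg$costs$mode)) "bf_reweighted"
                            else cfg$costs$mode,
                     normalize = isTRUE(cfg$costs$normalize))
  p3 <- if (is.null(cfg$phase3)) phase3_spec() else {
    check_keys(cfg$phase3, schema_keys$phase3, "phase3")
    do.call(phase3_spec, cfg$phase3)
  }
  num <- cfg$numerics
  if (!is.null(num)) check_keys(num, schema_keys$numerics, "numerics")
  grab <- function(key, default) if (is.null(num[[key]])) default
                                 else num[[key]]
  control <- oc_control(theta_nodes = grab("theta_nodes", 199L),
                        outcome_nodes = grab("outcome_nodes", 801L),
                        gh_order = grab("gh_order", 199L))
  n_grid <- if (is.null(num$n_grid)) {
    if (model$family == "binomial") seq(1L, 150L) else seq(2L, 300L, 2L)
  } else parse_ngrid(num$n_grid, "numerics.n_grid")
  el <- cfg$elicitation
  if (!is.null(el)) {
    check_keys(el, schema_keys$elicitation, "elicitation")
    if (is.null(el$analysis_prior) || !el$analysis_prior %in% names(priors))
      stop("'elicitation.analysis_prior' must name an analysis prior")
    if (!is.null(el$elicit_grid))
      el$elicit_grid <- parse_ngrid(el$elicit_grid,
                                    "elicitation.elicit_grid")
  }
  structure(list(model = model, hyp = hyp, analysis_priors = priors,
                 sampling = sp, sampling_grid = cfg$sampling$grid,
                 costs = costs, phase3 = p3, elicitation = el,
                 control = control, n_grid = n_grid,
                 eval_n = grab("eval_n", NULL), seed = grab("seed", 1L),
                 raw = cfg, path = path),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>", x$model$family, "outcome; theta0 =", x$hyp$theta0,
      ", thetaR =", x$hyp$thetaR, "\n  analysis priors:",
      paste(names(x$analysis_priors), collapse = ", "), "\n")
  invisible(x)
}

#' Paths to the bundled example scenarios
#'
#' Two complete scenario configurations ship with the package: a normal
#' simulation study (`"normal_vague"`: vague, informative, robust mixture
#' and EB power analysis priors with informative sampling prior
#' N(0.25, 1/50)) and a single-arm binomial proof-of-concept trial
#' (`"binomial_poc"`: non-small-cell lung cancer objective response rate,
#' rate-matched RSN prior Beta(0.0811, 1), informative Beta(11, 29)).
#'
#' @param name Scenario name, or `NULL` to list available names.
#' @return A file path (or vector of names).
#' @export
trialrisk_scenarios <- function(name = NULL) {
  dir <- system.file("extdata", package = "trialrisk")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop("unknown scenario '", name, "'; available: ",
         paste(avail, collapse = ", "))
  file.path(dir, paste0(name, ".yaml"))
}

## Build the SATE/AMSE curves used for cost elicitation under the prior the
## scenario names, then elicit the costs.
scenario_elicit <- function(sc) {
  el <- sc$elicitation
  if (is.null(el)) stop("the scenario has no 'elicitation' block")
  grid <- if (!is.null(el$elicit_grid)) el$elicit_grid else sc$n_grid
  prior <- sc$analysis_priors[[el$analysis_prior]]
  curve <- oc_curve(prior, sc$model, sc$costs, sc$hyp, sc$sampling,
                    sc$phase3, grid, sc$control)
  ns <- el$n_sate
  na <- el$n_amse
  if (is.null(ns) || is.null(na)) {
    gn <- goal_n(curve, sate_targets = el$sate_targets,
                 amse_targets = el$amse_targets)
    if (is.null(ns)) ns <- gn$n_sate
    if (is.null(na)) na <- gn$n_amse
  }
  list(curve = curve,
       costs = elicit_costs(ns, na, curve$sate, curve$amse, grid,
                            smooth_sate = isTRUE(el$smooth_sate),
                            smooth_amse = isTRUE(el$smooth_amse),
                            bandwidth = el$bandwidth))
}

#' Run a scenario pipeline
#'
#' Executes one of the standard commands on a loaded scenario:
#' \describe{
#'   \item{`evaluate`}{[averaged_oc()] for every analysis prior at a fixed
#'     sample size (`n` or the scenario's `eval_n`).}
#'   \item{`elicit-costs`}{OC curves under the scenario's elicitation prior
#'     and [elicit_costs()] at its target sample sizes.}
#'   \item{`design`}{cost elicitation, then risk minimization over the
#'     scenario sample-size grid for every analysis prior.}
#'   \item{`sensitivity`}{[sensitivity_scan()] over the scenario's sampling
#'     grid, reusing one cost elicitation.}
#'   \item{`reproduce`}{the full pipeline: elicited costs, key averaged
#'     operating characteristics at the elicitation sample sizes, and the
#'     selected design.}
#' }
#' When `out_dir` is given, tables are written as CSV, scalar results as
#' JSON, and the resolved configuration is echoed alongside them.
#'
#' @param sc A `scenario` from [load_scenario()].
#' @param command One of `"evaluate"`, `"elicit-costs"`, `"design"`,
#'   `"sensitivity"`, `"reproduce"`.
#' @param n Sample size override for `evaluate`.
#' @param out_dir Optional output directory.
#' @param seed Random seed (stored computations are deterministic; the seed
#'   fixes any Monte-Carlo auxiliaries and is echoed for provenance).
#' @return The command's result, invisibly when written to `out_dir`.
#' @export
run_scenario <- function(sc, command = c("evaluate", "elicit-costs",
                                         "design", "sensitivity",
                                         "reproduce"),
                         n = NULL, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(sc, "scenario"))
  command <- match.arg(command)
  set.seed(if (is.null(seed)) sc$seed else seed)
  res <- switch(command,
    "evaluate" = {
      n_eval <- if (!is.null(n)) n else sc$eval_n
      if (is.null(n_eval)) stop("'evaluate' needs a sample size: give 'n'")
      tab <- do.call(rbind, lapply(names(sc$analysis_priors), function(nm) {
        oc <- averaged_oc(sc$analysis_priors[[nm]], sc$model, n_eval,
                          sc$costs, sc$hyp, sc$sampling, sc$phase3,
                          sc$control)
        cbind(data.frame(analysis_prior = nm), as.data.frame(unclass(oc)))
      }))
      list(oc = tab)
    },
    "elicit-costs" = scenario_elicit(sc),
    "design" = {
      ec <- scenario_elicit(sc)
      designs <- lapply(names(sc$analysis_priors), function(nm) {
        cv <- oc_curve(sc$analysis_priors[[nm]], sc$model, sc$costs,
                       sc$hyp, sc$sampling, sc$phase3, sc$n_grid,
                       sc$control)
        cv <- integrated_risk(cv, ec$costs)
        opt <- suppressWarnings(optimal_n(cv))
        list(curve = cv, design = opt)
      })
      names(designs) <- names(sc$analysis_priors)
      list(costs = ec$costs, designs = designs)
    },
    "sensitivity" = {
      ec <- scenario_elicit(sc)
      sp_grid <- scenario_sampling_grid(sc)
      tab <- sensitivity_scan(sc$analysis_priors, sp_grid, sc$model,
                              sc$costs, ec$costs, sc$hyp, sc$phase3,
                              n_grid = sc$n_grid, control = sc$control)
      list(costs = ec$costs, sensitivity = tab)
    },
    "reproduce" = {
      ec <- scenario_elicit(sc)
      grid <- if (!is.null(sc$elicitation$elicit_grid))
        sc$elicitation$elicit_grid else sc$n_grid
      at <- function(nn) ec$curve[match(nn, grid), ]
      prior <- sc$analysis_priors[[sc$elicitation$analysis_prior]]
      cv <- oc_curve(prior, sc$model, sc$costs, sc$hyp, sc$sampling,
                     sc$phase3, sc$n_grid, sc$control)
      cv <- integrated_risk(cv, ec$costs)
      opt <- suppressWarnings(optimal_n(cv))
      list(costs = ec$costs,
           oc_at_n_sate = at(ec$costs$n_sate),
           oc_at_n_amse = at(ec$costs$n_amse),
           design = opt)
    })
  if (!is.null(out_dir)) {
    write_results(res, sc, command, out_dir)
    return(invisible(res))
  }
  res
}

scenario_sampling_grid <- function(sc) {
  g <- sc$sampling_grid
  if (is.null(g))
    stop("the scenario's 'sampling' block has no 'grid' entry")
  base <- sc$sampling$base
  if (base$variant == "normal") {
    means <- seq(g$mean_from, g$mean_to, length.out = g$points)
    sps <- lapply(means, function(m)
      sampling_prior(normal_prior(m, base$var)))
  } else {
    means <- seq(g$mean_from, g$mean_to, length.out = g$points)
    s <- base$a + base$b
    sps <- lapply(means, function(m)
      sampling_prior(beta_prior(m * s, (1 - m) * s)))
  }
  names(sps) <- signif(means, 4)
  sps
}

write_results <- function(res, sc, command, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  put_csv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  put_json <- function(x, name)
    jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(res$oc)) put_csv(res$oc, "oc_curve")
  if (!is.null(res$curve)) put_csv(as.data.frame(res$curve), "oc_curve")
  if (!is.null(res$costs)) put_json(unclass(res$costs), "costs")
  if (!is.null(res$sensitivity))
    put_csv(as.data.frame(res$sensitivity), "sensitivity")
  if (!is.null(res$designs)) {
    put_csv(do.call(rbind, lapply(names(res$designs), function(nm)
      cbind(data.frame(analysis_prior = nm),
            as.data.frame(res$designs[[nm]]$curve)))), "risk_curve")
    put_json(lapply(res$designs, function(d)
      list(n_opt = d$design$n_opt, risk = d$design$risk_at_opt)), "design")
  }
  if (!is.null(res$design) && inherits(res$design, "design_result"))
    put_json(list(n_opt = res$design$n_opt,
                  risk = res$design$risk_at_opt), "design")
  writeLines(yaml::as.yaml(sc$raw),
             file.path(out_dir, "resolved_config.yaml"))
  invisible(NULL)
}
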