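# Shared fixtures: the two study scenarios used throughout the suite.

normal_setup <- function() {
  list(model = trial_model("normal", 1),
       hyp = hypotheses(0, 0.15),
       costs = cost_spec(0.05, 0.95),
       vague = normal_prior(0, 100),
       informative = normal_prior(0.25, 1 / 50),
       mixture = mixture_prior(list(normal_prior(0.25, 1 / 50),
                                    normal_prior(0.25, 100)), c(0.5, 0.5)),
       eb = power_prior(historical_data(50, mean = 0.25),
                        normal_prior(0, 100), "empirical_bayes"),
       sp = sampling_prior(normal_prior(0.25, 1 / 50)))
}

binomial_setup <- function() {
  list(model = trial_model("binomial"),
       hyp = hypotheses(0.075, 0.175),
       costs = cost_spec(0.05, 0.95),
       rsn = beta_prior(0.0811, 1),
       informative = beta_prior(11, 29),
       mixture = mixture_prior(list(beta_prior(11, 29), beta_prior(1, 1)),
                               c(0.5, 0.5)),
       eb = power_prior(historical_data(38, successes = 10, failures = 28),
                        beta_prior(1, 1), "empirical_bayes"),
       sp = sampling_prior(beta_prior(11, 29)))
}

# Riemann-sum average of f over a truncated normal/beta density: slow
# independent check for the quadrature averaging path.
riemann_average <- function(f, dens, lo, hi, k = 1e5) {
  x <- seq(lo, hi, length.out = k)
  w <- dens(x)
  sum(f(x) * w) / sum(w)
}
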