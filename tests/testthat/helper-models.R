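# Shared fixtures, built in code at load time.

bd_model <- example_model("birth_death")

# the reference birth-death dataset: one SSA trajectory at k = 1,
# gamma = 0.1, 30 observation times, observation noise sd 1
bd_data <- generate_fixture("birth_death", seed = 7)

bd_fsp_cfg <- fsp_config(60)

# log-spaced grid across the full prior box for the FSP oracle
bd_grid <- exp(seq(log(0.01), log(100), length.out = 400))

# analytic 1-D Gaussian-bump likelihood on a uniform prior: evidence and
# posterior moments in closed form (integral of the bump over the box)
gauss_bump_model <- function(mu = 0.5, s = 0.05) {
  prior <- prior_spec("a", "uniform", 0, 1)
  loglik <- function(th) stats::dnorm(th[1], mu, s, log = TRUE)
  logZ <- log(stats::pnorm(1, mu, s) - stats::pnorm(0, mu, s))
  list(model = list(prior = prior), loglik = loglik, logZ = logZ,
       post_mean = mu)
}

# minimal placeholder dataset for runs driven entirely by loglik_fn
dummy_data <- timeseries_data(list(c(1)), list(matrix(0)))

weighted_mean <- function(x, w) sum(x * w) / sum(w)
weighted_var <- function(x, w) {
  w <- w / sum(w)
  sum(w * (x - sum(x * w))^2)
}
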