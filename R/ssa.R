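#' Mass-action reaction propensities
#'
#' Evaluates \eqn{a_j(x) = c_j \prod_i {x_i \choose p_{ji}}} for every
#' reaction, where the counting convention is the number of distinct
#' reactant multisets (so a dimerization \code{2X -> ...} at rate c in
#' state x has propensity \code{c * x * (x - 1) / 2}). A propensity is zero
#' whenever some \code{x_i < p_ji}.
#'
#' @param network an \code{lfns_network}.
#' @param x non-negative integer state vector.
#' @param theta parameter vector (inferred rates, in \code{par_names} order).
#' @return numeric vector of length \code{n_R}.
#' @export
propensities <- function(network, x, theta) {
  stopifnot(inherits(network, "lfns_network"))
  if (any(x < 0)) stop("state must be non-negative")
  rates <- rates_from_theta(network, theta)
  a <- numeric(network$n_R)
  for (j in seq_len(network$n_R)) {
    aj <- rates[j]
    for (i in seq_len(network$n_x)) {
      p <- network$Pre[j, i]
      if (p > 0) aj <- aj * choose(x[i], p)
    }
    a[j] <- aj
  }
  a
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Simulates one realization of the network's jump process and records the
#' state at the requested grid times (the state at the last jump at or
#' before each grid time). Waiting times are exponential with rate equal to
#' the total propensity and the fired reaction is chosen proportionally to
#' its propensity. A state with zero total propensity is absorbing and is
#' held constant to the end of the grid.
#'
#' Randomness comes from R's global RNG stream; call \code{set.seed} for
#' reproducible paths.
#'
#' @param network an \code{lfns_network}.
#' @param theta parameter vector.
#' @param x0 initial state (defaults to the network's \code{x0}).
#' @param t_grid increasing vector of times at which to record the state.
#' @param t0 model start time (default 0).
#' @param record_jumps if \code{TRUE}, also return every jump time/state.
#' @param max_events guard on the number of reaction events.
#' @return a list with \code{t_grid}, integer matrix \code{grid_states}
#'   (\code{length(t_grid) x n_x}) and, if requested, \code{jump_times} and
#'   \code{jump_states}.
#' @export
simulate_ssa <- function(network, theta, x0 = network$x0, t_grid,
                         t0 = 0, record_jumps = FALSE, max_events = 1e8) {
  stopifnot(inherits(network, "lfns_network"))
  if (length(t_grid) > 1 && any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing")
  if (any(t_grid < t0)) stop("t_grid must not precede t0")
  if (any(x0 < 0) || any(x0 != round(x0))) stop("x0 must be non-negative integers")
  rates <- rates_from_theta(network, theta)
  out <- ssa_simulate_cpp(as.numeric(rates), network$Pre, network$Stoich,
                          as.integer(x0), as.numeric(t_grid), t0,
                          record_jumps, max_events)
  out$t_grid <- t_grid
  colnames(out$grid_states) <- network$species
  out
}

# ---- in-package example models ------------------------------------------

#' Built-in example models
#'
#' Constructs the model bundles used throughout the documentation and test
#' suite:
#' \describe{
#'   \item{birth_death}{one species produced at rate \code{k} and degraded
#'     at rate \code{gamma}; defaults \code{k = 1}, \code{gamma = 0.1}
#'     (fixed), log-uniform prior on \code{k} over \code{[0.01, 100]};
#'     the species count is observed directly.}
#'   \item{transcription}{a two-state gene (rates \code{k_on},
#'     \code{k_off}); while on, transcription initiates at rate \code{k_r}
#'     and each nascent RNA traverses 8 sequential stages at rate
#'     \code{lambda} per stage before release to an unobserved sink, so a
#'     transcription event occupies the observable region for an
#'     Erlang(8, lambda) time (mean \code{8/lambda}); the observed channel
#'     is the total nascent RNA (sum of the 8 stages).}
#'   \item{lotka_volterra}{prey birth, predation and predator death with
#'     both species observed.}
#' }
#'
#' @param name one of \code{"birth_death"}, \code{"transcription"},
#'   \code{"lotka_volterra"}.
#' @return list with \code{network}, \code{obs}, \code{prior} and
#'   \code{theta_true} (the default data-generating parameters).
#' @export
example_model <- function(name = c("birth_death", "transcription", "lotka_volterra")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "lfns")
  if (path == "") stop("missing packaged model config for ", name)
  m <- load_model(path)
  m$theta_true <- switch(name,
    birth_death = c(k = 1),
    # artifact defaults: lambda = 4/min so the 8 stages take 8/lambda = 2 min
    transcription = c(k_on = 0.05, k_off = 0.1, k_r = 2, lambda = 4),
    lotka_volterra = c(c1 = 1, c2 = 0.005, c3 = 0.6))
  m
}

#' Generate a synthetic observation dataset
#'
#' Simulates \code{M} independent SSA trajectories of a named example model
#' and applies the model's linear read-out with additive Gaussian noise of
#' standard deviation \code{noise_sigma} to produce an observation set.
#'
#' @param name example model name (see [example_model()]).
#' @param theta data-generating parameter vector (defaults to the model's
#'   \code{theta_true}).
#' @param M number of trajectories.
#' @param t_grid observation times (strictly increasing, > 0).
#' @param noise_sigma observation noise SD (overrides the model config's
#'   per-channel sigma for data generation when non-NULL; \code{0} gives
#'   the exact integer read-out).
#' @param seed integer seed; the call is reproducible for a fixed seed.
#' @return an \code{lfns_timeseries} with \code{M} trajectories.
#' @export
generate_fixture <- function(name, theta = NULL, M = 1,
                             t_grid = NULL, noise_sigma = NULL, seed = 1L) {
  model <- example_model(name)
  if (is.null(theta)) theta <- model$theta_true
  if (is.null(t_grid))
    t_grid <- switch(name,
      birth_death = seq(1, 30, by = 1),
      transcription = seq(0.5, 30, by = 0.5),
      lotka_volterra = seq(0.5, 15, by = 0.5))
  sig <- if (is.null(noise_sigma)) model$obs$sigma else
    rep_len(noise_sigma, model$obs$n_y)
  set.seed(as.integer(seed))
  times <- vector("list", M); y <- vector("list", M)
  for (i in seq_len(M)) {
    path <- simulate_ssa(model$network, theta, t_grid = t_grid)
    mu <- path$grid_states %*% t(model$obs$C)
    noise <- matrix(stats::rnorm(length(mu), sd = rep(sig, each = nrow(mu))),
                    nrow = nrow(mu))
    times[[i]] <- t_grid
    y[[i]] <- mu + noise
  }
  timeseries_data(times, y)
}
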