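#' Pseudo-marginal particle MCMC
#'
#' Metropolis-Hastings on the parameter vector with the likelihood in the
#' acceptance ratio replaced by its particle-filter estimate. The stored
#' estimate of the current state is reused, never refreshed — the
#' pseudo-marginal exactness condition, which makes the chain target the
#' same posterior as if the exact likelihood were used, for any H.
#' Proposals are a fixed symmetric Gaussian random walk; candidates
#' outside the prior box are rejected outright.
#'
#' @param model model bundle (\code{network}, \code{obs}, \code{prior}).
#' @param data an \code{lfns_timeseries}.
#' @param theta0 initial parameter vector (must have positive prior
#'   density).
#' @param Sigma proposal covariance (d x d symmetric positive definite, or
#'   a single variance for d = 1).
#' @param n_steps chain length.
#' @param H particle-filter particle count.
#' @param t0 model start time.
#' @param loglik_fn optional replacement for the particle-filter
#'   log-likelihood, \code{function(theta)} (used by tests with analytic
#'   likelihoods).
#' @return data.frame chain: theta columns, \code{loglik} (the stored
#'   estimate) and \code{accepted}.
#' @export
run_pmcmc <- function(model, data, theta0, Sigma, n_steps = 1000L,
                      H = 100L, t0 = 0, loglik_fn = NULL) {
  prior <- model$prior
  d <- prior$d
  if (length(theta0) != d) stop("theta0 has wrong length")
  if (!is.finite(prior_logdensity(prior, theta0)))
    stop("theta0 must lie inside the prior support")
  if (d == 1) Sigma <- matrix(Sigma, 1, 1)
  L <- t(chol(Sigma))
  ll <- if (is.null(loglik_fn))
    function(th) pf_loglikelihood(model$network, model$obs, th, data,
                                  H = H, t0 = t0) else loglik_fn
  cur_theta <- theta0
  cur_ll <- ll(cur_theta)
  cur_lp <- prior_logdensity(prior, cur_theta)
  out_theta <- matrix(NA_real_, n_steps, d)
  out_ll <- numeric(n_steps); out_acc <- logical(n_steps)
  for (s in seq_len(n_steps)) {
    cand <- cur_theta + drop(L %*% stats::rnorm(d))
    lp <- prior_logdensity(prior, cand)
    acc <- FALSE
    if (is.finite(lp)) {
      cand_ll <- ll(cand)
      logratio <- (cand_ll + lp) - (cur_ll + cur_lp)
      if (is.finite(logratio) && log(stats::runif(1)) < logratio) {
        cur_theta <- cand; cur_ll <- cand_ll; cur_lp <- lp; acc <- TRUE
      } else if (logratio == Inf) {  # -Inf current estimate, finite candidate
        cur_theta <- cand; cur_ll <- cand_ll; cur_lp <- lp; acc <- TRUE
      }
    }
    out_theta[s, ] <- cur_theta; out_ll[s] <- cur_ll; out_acc[s] <- acc
  }
  df <- data.frame(out_theta)
  names(df) <- prior$name
  df$loglik <- out_ll
  df$accepted <- out_acc
  df
}

#' ABC sequential Monte Carlo
#'
#' Approximate Bayesian computation targeting
#' \code{p(theta | d(y_theta, y) < eps)} through a decreasing threshold
#' schedule: round 0 samples the prior and simulates a synthetic dataset
#' per particle; each later round sets the next threshold to a quantile
#' (default 30%) of the previous round's accepted distances, resamples
#' ancestors by weight, perturbs with a Gaussian kernel whose variance is
#' twice the weighted sample variance, and accepts candidates whose
#' simulated dataset lies within the threshold. Distance is the euclidean
#' norm between simulated and observed observation matrices stacked over
#' the shared time grid (no summary statistics). Weights are the standard
#' SMC importance weights prior/(sum w_j K(theta | theta_j)).
#'
#' @param model model bundle.
#' @param data observed \code{lfns_timeseries}; simulated datasets use the
#'   same time grids and observation noise.
#' @param n_particles population size (>= 10).
#' @param quantile threshold schedule quantile in (0, 1).
#' @param rounds number of threshold-shrinking rounds after round 0.
#' @param eps_final optional early stop once the threshold drops below
#'   this value.
#' @param t0 model start time.
#' @param max_attempts simulation budget per round; on a stall the
#'   current population is returned with a warning.
#' @return list with \code{theta} (matrix), \code{weight}, \code{distance},
#'   \code{eps_schedule} (thresholds eps_1..eps_R, strictly decreasing)
#'   and \code{rounds_completed}.
#' @export
run_abcsmc <- function(model, data, n_particles = 100L, quantile = 0.30,
                       rounds = 5L, eps_final = 0, t0 = 0,
                       max_attempts = 1e6) {
  if (n_particles < 10) stop("ABC-SMC needs at least 10 particles")
  if (!(quantile > 0 && quantile < 1)) stop("quantile must be in (0, 1)")
  prior <- model$prior
  d <- prior$d
  simulate_distance <- function(theta) {
    tot <- 0
    for (i in seq_len(data$M)) {
      path <- simulate_ssa(model$network, theta, t_grid = data$times[[i]], t0 = t0)
      mu <- path$grid_states %*% t(model$obs$C)
      ysim <- mu + matrix(stats::rnorm(length(mu),
                                       sd = rep(model$obs$sigma, each = nrow(mu))),
                          nrow = nrow(mu))
      tot <- tot + sum((ysim - data$y[[i]])^2)
    }
    sqrt(tot)
  }
  theta <- sample_prior(prior, n_particles, drop = FALSE)
  dist <- vapply(seq_len(n_particles), function(k) simulate_distance(theta[k, ]),
                 numeric(1))
  weight <- rep(1 / n_particles, n_particles)
  eps_schedule <- numeric(0)
  rounds_completed <- 0L
  for (rd in seq_len(rounds)) {
    eps <- unname(stats::quantile(dist, quantile))
    eps_schedule <- c(eps_schedule, eps)
    # Gaussian perturbation kernel, variance = 2 x weighted sample variance
    wmean <- colSums(theta * weight)
    wvar <- colSums(sweep(theta, 2, wmean)^2 * weight)
    ksd <- sqrt(pmax(2 * wvar, 1e-12))
    new_theta <- matrix(NA_real_, n_particles, d)
    new_dist <- numeric(n_particles)
    attempts <- 0L; stalled <- FALSE
    for (k in seq_len(n_particles)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) { stalled <- TRUE; break }
        anc <- sample.int(n_particles, 1, prob = weight)
        cand <- theta[anc, ] + stats::rnorm(d, sd = ksd)
        if (!is.finite(prior_logdensity(prior, cand))) next
        dc <- simulate_distance(cand)
        if (dc < eps) { new_theta[k, ] <- cand; new_dist[k] <- dc; break }
      }
      if (stalled) break
    }
    if (stalled) {
      warning("ABC-SMC round ", rd, " stalled; returning the previous population")
      break
    }
    # importance weights: prior density over kernel mixture density
    logw <- vapply(seq_len(n_particles), function(k) {
      lp <- prior_logdensity(prior, new_theta[k, ])
      lk <- log(sum(weight * exp(rowSums(
        stats::dnorm(sweep(theta, 2, new_theta[k, ], function(a, b) b - a),
                     sd = rep(ksd, each = n_particles), log = TRUE)))))
      lp - lk
    }, numeric(1))
    weight <- exp(logw - logsumexp(logw))
    theta <- new_theta; dist <- new_dist
    rounds_completed <- rd
    if (eps <= eps_final) break
  }
  colnames(theta) <- prior$name
  list(theta = theta, weight = weight, distance = dist,
       eps_schedule = eps_schedule, rounds_completed = rounds_completed)
}
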