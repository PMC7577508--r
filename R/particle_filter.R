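#' Bootstrap particle filter likelihood estimate
#'
#' Computes one realization of the particle-filter estimate of the
#' log-likelihood \eqn{\log \hat{l}(\theta)} of a parameter vector for a set
#' of observed trajectories. Per trajectory, \code{H} state particles start
#' at the model's initial state; between observation times each particle is
#' propagated by exact SSA, weighted by the observation density
#' \eqn{p(y_t | x)}, the log of the mean weight is accumulated, and the
#' particle set is multinomially resampled proportionally to the weights.
#' Trajectories are independent, so their log-estimates add.
#'
#' The linear-domain estimate \eqn{\exp} of the returned value is an
#' unbiased estimator of the true likelihood; the returned log value itself
#' is *not* an unbiased estimator of the log-likelihood (Jensen gap).
#' If at some step every particle has zero observation density the estimate
#' is exactly zero and \code{-Inf} is returned (a valid value, not an
#' error).
#'
#' @param network an \code{lfns_network}.
#' @param obs an \code{lfns_obsmodel}.
#' @param theta parameter vector.
#' @param data an \code{lfns_timeseries}.
#' @param H number of particles (>= 1).
#' @param t0 model start time shared by all trajectories.
#' @return a single log-likelihood-estimate value (possibly \code{-Inf}).
#' @export
pf_loglikelihood <- function(network, obs, theta, data, H = 100L, t0 = 0) {
  stopifnot(inherits(network, "lfns_network"), inherits(obs, "lfns_obsmodel"),
            inherits(data, "lfns_timeseries"))
  if (H < 1) stop("particle filter needs H >= 1")
  if (any(!is.finite(theta))) stop("theta must be finite")
  rates <- rates_from_theta(network, theta)
  total <- 0
  for (i in seq_len(data$M)) {
    ll <- pf_loglik_cpp(as.numeric(rates), network$Pre, network$Stoich,
                        network$x0, as.numeric(data$times[[i]]),
                        data$y[[i]], obs$C, obs$sigma, as.integer(H),
                        t0, 1e8)
    if (!is.finite(ll)) return(-Inf)
    total <- total + ll
  }
  total
}

#' Replicate particle-filter estimates
#'
#' Draws independent realizations of the particle-filter log-likelihood
#' estimate at a fixed parameter vector, for diagnostics of the estimator
#' spread as a function of \code{H}.
#'
#' @inheritParams pf_loglikelihood
#' @param reps number of independent replicates (>= 1).
#' @return numeric vector of \code{reps} log-estimates.
#' @export
pf_estimate_distribution <- function(network, obs, theta, data, H = 100L,
                                     reps = 100L, t0 = 0) {
  if (reps < 1) stop("reps must be >= 1")
  vapply(seq_len(reps), function(i)
    pf_loglikelihood(network, obs, theta, data, H = H, t0 = t0), numeric(1))
}
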