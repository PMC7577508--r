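#' Initialize the live set
#'
#' Draws N particles from the joint prior: each particle is a prior draw
#' of the parameter vector paired with one realization of the
#' particle-filter likelihood estimator at that parameter.
#'
#' @param model model bundle (list with \code{network}, \code{obs},
#'   \code{prior}) as returned by [load_model()] or [example_model()].
#' @param data an \code{lfns_timeseries}.
#' @param N number of live particles (>= 2).
#' @param H particle-filter particle count.
#' @param t0 model start time.
#' @param loglik_fn optional replacement for the particle-filter estimator:
#'   a \code{function(theta)} returning one log likelihood-estimate draw
#'   (used with analytic or mock likelihoods; LF-NS itself is agnostic to
#'   which unbiased estimator supplies the values).
#' @return list of class \code{lfns_liveset} with \code{theta} (N x d
#'   matrix) and \code{loglik} (length N).
#' @export
initialize_live <- function(model, data, N, H = 100L, t0 = 0,
                            loglik_fn = NULL) {
  if (N < 2) stop("need at least 2 live particles")
  ll <- if (is.null(loglik_fn))
    function(th) pf_loglikelihood(model$network, model$obs, th, data,
                                  H = H, t0 = t0) else loglik_fn
  theta <- sample_prior(model$prior, N, drop = FALSE)
  loglik <- vapply(seq_len(N), function(k) ll(theta[k, ]), numeric(1))
  structure(list(theta = theta, loglik = loglik, N = N),
            class = "lfns_liveset")
}

#' One LF-NS iteration
#'
#' Removes the r lowest-likelihood particles (recorded as r sequential
#' single removals with live counts N, N-1, ..., N-r+1), sets the
#' threshold eps to the highest removed value, refits the proposal model
#' to the surviving live points, and refills the live set: each candidate
#' is a prior-restricted-to-support parameter draw paired with one fresh
#' particle-filter estimate, accepted iff its estimate exceeds eps
#' (strictly; exact ties are rejections, and a run of 1e5 consecutive tie
#' rejections raises a plateau error). This rejection construction is what
#' samples the joint prior constrained to estimates above eps.
#'
#' @param live an \code{lfns_liveset}.
#' @param model model bundle.
#' @param data observations.
#' @param r batch size (1 <= r < N).
#' @param sampler proposal kind: \code{"gmm"} (alias \code{"dpgmm"}),
#'   \code{"ellipsoid"} or \code{"prior"}.
#' @param H particle-filter particle count.
#' @param t0 model start time.
#' @param max_attempts rejection budget for the whole refill.
#' @param loglik_fn optional estimator override, see [initialize_live()].
#' @return list with the updated \code{live} set, \code{dead} (data.frame
#'   of removed particles: theta columns, \code{loglik}, \code{live_count}),
#'   \code{acceptance} (r / particle-filter evaluations), and
#'   \code{attempts}.
#' @export
lfns_step <- function(live, model, data, r = 10L, sampler = "gmm",
                      H = 100L, t0 = 0, max_attempts = 1e6,
                      loglik_fn = NULL) {
  ll <- if (is.null(loglik_fn))
    function(th) pf_loglikelihood(model$network, model$obs, th, data,
                                  H = H, t0 = t0) else loglik_fn
  N <- live$N
  if (r < 1 || r >= N) stop("need 1 <= r < N")
  ord <- order(live$loglik)
  low <- ord[seq_len(r)]
  dead <- data.frame(live$theta[low, , drop = FALSE])
  names(dead) <- model$prior$name
  dead$loglik <- live$loglik[low]
  dead$live_count <- N - seq_len(r) + 1L
  eps <- max(dead$loglik)

  keep_theta <- live$theta[-low, , drop = FALSE]
  keep_loglik <- live$loglik[-low]
  prop <- fit_proposal(keep_theta, kind = sampler, prior = model$prior)

  new_theta <- matrix(NA_real_, r, ncol(live$theta))
  new_loglik <- numeric(r)
  pf_evals <- 0L; tie_run <- 0L
  for (k in seq_len(r)) {
    repeat {
      cand <- sample_support_uniform_prior(prop, model$prior,
                                           max_attempts = max_attempts)
      lhat <- ll(cand$theta)
      pf_evals <- pf_evals + 1L
      if (pf_evals > max_attempts)
        stop("replacement sampling exhausted its evaluation budget")
      if (lhat > eps) { tie_run <- 0L; break }
      if (lhat == eps) {
        tie_run <- tie_run + 1L
        if (tie_run >= 1e5)
          stop("likelihood plateau detected: 1e5 consecutive ties at the threshold")
      } else tie_run <- 0L
    }
    new_theta[k, ] <- cand$theta
    new_loglik[k] <- lhat
  }
  live$theta <- rbind(keep_theta, new_theta)
  live$loglik <- c(keep_loglik, new_loglik)
  list(live = live, dead = dead, acceptance = r / pf_evals,
       attempts = pf_evals)
}

#' Run likelihood-free nested sampling
#'
#' Full inference loop: initializes N live particles from the joint prior,
#' iterates [lfns_step()], and after every iteration updates the dead+live
#' evidence estimate, its variance, the lower variance bound and the
#' termination statistic. The run stops when the termination statistic
#' falls below \code{delta} or after \code{max_iter} iterations (the
#' estimator is unbiased at any stopping iteration, so hitting
#' \code{max_iter} returns a usable result with \code{converged = FALSE}).
#'
#' Posterior samples combine dead particles (weight
#' \code{exp(loglik) * w_i}) and live particles (weight
#' \code{x_hat_m * exp(loglik) / N}), normalized by the evidence estimate.
#'
#' @inheritParams lfns_step
#' @param N live-set size.
#' @param delta termination threshold on the statistic (> 0).
#' @param max_iter iteration cap (each iteration removes r particles).
#' @param form termination statistic form, see [delta_lfns()].
#' @param seed integer seed driving all randomness of the run.
#' @param loglik_fn optional estimator override, see [initialize_live()].
#' @param verbose print one line per iteration.
#' @return object of class \code{lfns_run}: \code{trace} (one row per
#'   iteration), \code{posterior} (weighted samples), \code{evidence}
#'   (final \code{lfns_evidence}), \code{live}, \code{converged},
#'   \code{settings}.
#' @export
run_lfns <- function(model, data, N = 100L, H = 100L, r = 10L,
                     sampler = "gmm", delta = 0.001, max_iter = 1000L,
                     form = "sd", seed = 1L, t0 = 0, loglik_fn = NULL,
                     verbose = FALSE) {
  if (delta <= 0 && !is.finite(max_iter))
    stop("need delta > 0 or a finite max_iter")
  set.seed(as.integer(seed))
  live <- initialize_live(model, data, N, H = H, t0 = t0,
                          loglik_fn = loglik_fn)
  dead_loglik <- numeric(0); dead_counts <- integer(0)
  dead_theta <- NULL
  trace <- list()
  converged <- FALSE
  iter <- 0L
  repeat {
    est <- evidence_from_trace(dead_loglik, dead_counts, live$loglik)
    dl <- delta_lfns(est, form = form)
    if (iter > 0) {
      trace[[iter]] <- data.frame(
        iteration = iter,
        n_dead = est$m,
        eps = max(dead_loglik),
        log_xhat = est$log_xhat_m,
        logZ_D = est$logZ_D, logZ_L = est$logZ_L, logZ_tot = est$logZ_tot,
        log_var_tot = estimator_variance(est)$log_var,
        log_var_min = min_variance(est)$log_var,
        delta_lfns = dl,
        log_delta_max = delta_max(est, live$loglik)$log_delta_max,
        acceptance = last_acc, attempts = last_att)
      if (verbose)
        message(sprintf("iter %3d  eps %.3f  logZ %.4f  delta %.3g  acc %.3f",
                        iter, max(dead_loglik), est$logZ_tot, dl, last_acc))
      if (should_terminate(dl, delta)) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    step <- lfns_step(live, model, data, r = r, sampler = sampler,
                      H = H, t0 = t0, loglik_fn = loglik_fn)
    live <- step$live
    d <- ncol(live$theta)
    dead_theta <- rbind(dead_theta, as.matrix(step$dead[, seq_len(d), drop = FALSE]))
    dead_loglik <- c(dead_loglik, step$dead$loglik)
    dead_counts <- c(dead_counts, step$dead$live_count)
    last_acc <- step$acceptance; last_att <- step$attempts
    iter <- iter + 1L
  }
  if (!converged && max_iter > 0 && iter >= max_iter)
    warning("LF-NS hit max_iter before the termination statistic dropped below delta; ",
            "the returned estimate is still unbiased")
  est <- evidence_from_trace(dead_loglik, dead_counts, live$loglik)
  posterior <- lfns_posterior(model$prior, dead_theta, dead_loglik,
                              dead_counts, live, est)
  structure(list(
    trace = if (length(trace)) do.call(rbind, trace) else NULL,
    posterior = posterior, evidence = est, live = live,
    converged = converged,
    settings = list(N = N, H = H, r = r, sampler = sampler, delta = delta,
                    max_iter = max_iter, form = form, seed = seed)),
    class = "lfns_run")
}

#' @export
print.lfns_run <- function(x, ...) {
  cat(sprintf("LF-NS run: %d removals, log Z_tot = %.4f, converged = %s\n",
              x$evidence$m, x$evidence$logZ_tot, x$converged))
  invisible(x)
}

# assemble the weighted posterior sample from dead + live particles
lfns_posterior <- function(prior, dead_theta, dead_loglik, dead_counts,
                           live, est) {
  m <- length(dead_loglik)
  sm <- est$shrinkage
  log_xhat <- c(0, if (m > 0) cumsum(log(sm$mu)))
  log_w <- if (m > 0) log_xhat[seq_len(m)] + log1p(-sm$mu) else numeric(0)
  lw_dead <- if (m > 0) dead_loglik + log_w - est$logZ_tot else numeric(0)
  lw_live <- est$log_xhat_m + live$loglik - log(live$N) - est$logZ_tot
  theta <- rbind(if (m > 0) dead_theta, live$theta)
  df <- data.frame(theta)
  names(df) <- prior$name
  df$loglik <- c(dead_loglik, live$loglik)
  df$logweight <- c(lw_dead, lw_live)
  df$weight <- exp(df$logweight)
  df$weight <- df$weight / sum(df$weight)
  df$type <- c(rep("dead", m), rep("live", live$N))
  df
}
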