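#' Beta shrinkage moments
#'
#' Under nested sampling with \code{N_i} live points at the i-th removal,
#' the shrinkage factor \code{t_i = x_i / x_{i-1}} is the maximum of
#' \code{N_i} uniforms, i.e. Beta(N_i, 1), independently across removals.
#' This helper packages the per-removal first and second moments
#' \code{mu_i = N_i/(N_i+1)} and \code{nu_i = N_i/(N_i+2)} used by the
#' evidence point estimate and its variance.
#'
#' @param live_counts integer vector \code{N_1..N_m} of live-set sizes at
#'   each removal.
#' @return list with \code{mu}, \code{nu}, their cumulative products
#'   \code{cmu} (the mean prior volumes \code{x_hat_i}) and \code{cnu},
#'   and \code{logR1p = log(R_i)} where
#'   \code{R_i = E[x_i^2]/E[x_i]^2 = prod(1 + 1/(N_j (N_j + 2)))}.
#' @export
shrinkage_moments <- function(live_counts) {
  N <- as.numeric(live_counts)
  if (any(N < 1)) stop("live counts must be >= 1")
  mu <- N / (N + 1)
  nu <- N / (N + 2)
  list(mu = mu, nu = nu,
       cmu = cumprod(mu), cnu = cumprod(nu),
       logR = cumsum(log1p(1 / (N * (N + 2)))))
}

#' Evidence estimate from dead and live points
#'
#' The dead+live nested-sampling evidence estimator. With mean prior
#' volumes \code{x_hat_i = prod_{j<=i} N_j/(N_j+1)} (deterministic means,
#' not sampled) and shell weights \code{w_i = x_hat_{i-1} - x_hat_i}, the
#' dead-point part is \code{Z_D = sum_i exp(eps_i) w_i} and the live-point
#' part is \code{Z_L = x_hat_m * mean(exp(loglike))} over the current live
#' set; the total is their sum. All sums are carried in the log domain with
#' a common offset, so likelihoods on the scale of exp(-1000) are handled.
#'
#' @param dead_loglik numeric vector of dead-point log likelihood-estimate
#'   thresholds \code{eps_1..eps_m}, in removal order (may be empty).
#' @param dead_counts live-set size at each removal (same length).
#' @param live_loglik numeric vector of the current live set's log
#'   likelihood estimates (non-empty).
#' @return list of class \code{lfns_evidence} with log-domain fields
#'   \code{logZ_D}, \code{logZ_L}, \code{logZ_tot}, \code{log_Lbar},
#'   \code{log_varL} (log of var(exp(live))/N), the shrinkage summary, and
#'   the linear-domain conveniences \code{Z_D}, \code{Z_L}, \code{Z_tot}.
#' @export
evidence_from_trace <- function(dead_loglik, dead_counts, live_loglik) {
  m <- length(dead_loglik)
  if (length(dead_counts) != m) stop("dead_loglik and dead_counts lengths differ")
  if (length(live_loglik) == 0) stop("live set must be non-empty")
  N_live <- length(live_loglik)

  sm <- if (m > 0) shrinkage_moments(dead_counts) else
    list(mu = numeric(0), nu = numeric(0), cmu = numeric(0),
         cnu = numeric(0), logR = numeric(0))
  log_xhat <- c(0, if (m > 0) cumsum(log(sm$mu)))        # x_hat_0..x_hat_m
  # w_i = x_hat_{i-1} (1 - mu_i)
  log_w <- if (m > 0) log_xhat[seq_len(m)] + log1p(-sm$mu) else numeric(0)

  logZ_D <- if (m > 0) logsumexp(dead_loglik + log_w) else -Inf
  log_Lbar <- logsumexp(live_loglik) - log(N_live)
  logZ_L <- log_xhat[m + 1] + log_Lbar
  logZ_tot <- logsumexp(c(logZ_D, logZ_L))

  # sample variance of the linear-domain live likelihoods / N, log scale
  c0 <- max(live_loglik)
  log_varL <- if (N_live > 1 && is.finite(c0)) {
    lt <- exp(live_loglik - c0)
    v <- stats::var(lt) / N_live
    if (v > 0) 2 * c0 + log(v) else -Inf
  } else -Inf

  structure(list(logZ_D = logZ_D, logZ_L = logZ_L, logZ_tot = logZ_tot,
                 log_Lbar = log_Lbar, log_varL = log_varL,
                 log_xhat_m = log_xhat[m + 1], m = m,
                 dead_loglik = dead_loglik, dead_counts = dead_counts,
                 shrinkage = sm, N_live = N_live,
                 Z_D = exp(logZ_D), Z_L = exp(logZ_L), Z_tot = exp(logZ_tot)),
            class = "lfns_evidence")
}

#' @export
print.lfns_evidence <- function(x, ...) {
  cat(sprintf("Evidence estimate after %d removal(s): log Z_tot = %.4f (Z_D %.3g + Z_L %.3g)\n",
              x$m, x$logZ_tot, x$Z_D, x$Z_L))
  invisible(x)
}

# Core variance computation under the Beta-shrinkage model.
#
# V = sum_i eps~_i (x_{i-1} - x_i) + L * x_m,  x_i = prod_{j<=i} t_j,
# t_j ~ Beta(N_j, 1) independent, L independent with mean Lbar and
# variance varL.  Writing V = sum_{i=0}^m d_i x_i with
# d_0 = eps~_1, d_i = eps~_{i+1} - eps~_i, d_m = Lbar - eps~_m, we have
#   Var(V) = sum_{i,j} g_i g_j (R_{min(i,j)} - 1) + varL E[x_m^2],
# with g_i = d_i x_hat_i and R_i = E[x_i^2]/E[x_i]^2 >= 1.  Using suffix
# sums S_i = sum_{j>=i} g_j this collapses to the O(m) form
#   Var(V) = sum_i (R_i - 1) g_i (g_i + 2 S_{i+1}) + varL x_hat_m^2 R_m.
# R_i - 1 is computed via expm1 of accumulated log1p terms, so there is no
# catastrophic cancellation even when all N_j are large.
#
# All inputs/outputs are on a scale shifted by the common log offset c:
# eps~ = exp(dead_loglik - c) etc.; the caller tracks c.
.shrinkage_variance <- function(eps_lin, live_counts, Lbar_lin, varL_lin) {
  m <- length(eps_lin)
  if (m == 0) return(varL_lin)  # only the live-set Monte-Carlo term
  sm <- shrinkage_moments(live_counts)
  xhat <- c(1, sm$cmu)                       # x_hat_0..x_hat_m
  Rm1 <- c(0, expm1(sm$logR))                # R_0 - 1 = 0 (x_0 deterministic)
  d <- c(eps_lin[1], diff(eps_lin), Lbar_lin - eps_lin[m])
  g <- d * xhat
  S <- rev(cumsum(rev(g)))                   # S_i = sum_{j >= i} g_j
  Snext <- c(S[-1], 0)
  v <- sum(Rm1 * g * (g + 2 * Snext)) + varL_lin * xhat[m + 1]^2 * (Rm1[m + 1] + 1)
  max(v, 0)  # guard tiny negative round-off
}

#' Estimator variance under the Beta shrinkage model
#'
#' Closed-form variance of the dead+live evidence estimator
#' \eqn{\sum_i \tilde\epsilon_i (x_{i-1} - x_i) + x_m \bar{L}_m}, treating
#' the prior volumes as products of independent Beta(N_j, 1) shrinkage
#' factors and the live-set mean likelihood as an independent random
#' variable with variance \code{varL} (its Monte-Carlo variance,
#' \code{var(exp(live loglik))/N}). Uses
#' \eqn{E[x_i x_j] = \prod_{k \le i} \nu_k \prod_{i < k \le j} \mu_k}
#' for \eqn{i \le j}. Exact (no Monte Carlo), O(m).
#'
#' @param est an \code{lfns_evidence} from [evidence_from_trace()].
#' @param log_varL log of the live-set Monte-Carlo variance contribution;
#'   defaults to the value recorded in \code{est}. Use \code{-Inf} for the
#'   no-Monte-Carlo-noise lower bound.
#' @return list with \code{log_var} (log of the variance) and \code{var}.
#' @export
estimator_variance <- function(est, log_varL = est$log_varL) {
  stopifnot(inherits(est, "lfns_evidence"))
  c0 <- max(c(est$dead_loglik, est$log_Lbar), na.rm = TRUE)
  if (!is.finite(c0)) return(list(log_var = -Inf, var = 0))
  v <- .shrinkage_variance(exp(est$dead_loglik - c0), est$dead_counts,
                           exp(est$log_Lbar - c0),
                           exp(log_varL - 2 * c0))
  list(log_var = if (v > 0) 2 * c0 + log(v) else -Inf, var = v * exp(2 * c0))
}

#' Lower bound on the estimator variance
#'
#' The same variance but with the live-set Monte-Carlo term set to zero:
#' the lowest estimator variance still achievable by continuing the run.
#' It satisfies \code{var_tot >= var_min} and is monotone non-decreasing
#' in the iteration index m.
#'
#' @inheritParams estimator_variance
#' @return list with \code{log_var} and \code{var}.
#' @export
min_variance <- function(est) estimator_variance(est, log_varL = -Inf)

#' Termination statistic
#'
#' The normalized gap between the current estimator uncertainty and the
#' lowest uncertainty still achievable:
#' \code{delta = (sd_tot - sd_min) / Z_tot} (standard-deviation form, the
#' default) or \code{(var_tot - var_min) / Z_tot} (variance form, selected
#' with \code{form = "variance"}). Both are non-negative, zero when the
#' live-set Monte-Carlo variance vanishes, and shrink as the run
#' approaches its achievable accuracy; the run stops once
#' \code{delta < delta_threshold}.
#'
#' @param est an \code{lfns_evidence}.
#' @param form \code{"sd"} (default) or \code{"variance"}.
#' @return a single non-negative number.
#' @export
delta_lfns <- function(est, form = c("sd", "variance")) {
  form <- match.arg(form)
  if (!is.finite(est$logZ_tot)) stop("cannot normalize: Z_tot is zero")
  lv_tot <- estimator_variance(est)$log_var
  lv_min <- min_variance(est)$log_var
  if (form == "sd") {
    s_tot <- exp(lv_tot / 2 - est$logZ_tot)
    s_min <- exp(lv_min / 2 - est$logZ_tot)
    max(s_tot - s_min, 0)
  } else {
    max(exp(lv_tot - est$logZ_tot) - exp(lv_min - est$logZ_tot), 0)
  }
}

#' @rdname delta_lfns
#' @param delta value of the statistic.
#' @param threshold termination threshold.
#' @export
should_terminate <- function(delta, threshold) {
  is.finite(delta) && delta < threshold
}

#' Classical nested-sampling remainder bound
#'
#' \code{x_hat_m * max(exp(live loglik))}: the largest evidence mass the
#' unexplored prior volume could still hold, frequently used as a stopping
#' rule for plain nested sampling. Reported for comparison; never used to
#' stop a run here.
#'
#' @param est an \code{lfns_evidence}.
#' @param live_loglik the live set's log likelihood estimates.
#' @return list with \code{log_delta_max} and \code{delta_max}.
#' @export
delta_max <- function(est, live_loglik) {
  ld <- est$log_xhat_m + max(live_loglik)
  list(log_delta_max = ld, delta_max = exp(ld))
}
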