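#' Finite state projection configuration
#'
#' @param bounds integer vector of per-species truncation bounds; the state
#'   space is the box \code{0..bounds[i]} per species.
#' @param leak_tol maximum tolerated total probability leak out of the
#'   truncation over one likelihood evaluation, in (0, 1).
#' @return an object of class \code{lfns_fspconfig}.
#' @export
fsp_config <- function(bounds, leak_tol = 1e-8) {
  bounds <- as.integer(bounds)
  if (any(bounds < 0)) stop("truncation bounds must be non-negative")
  if (!(leak_tol > 0 && leak_tol < 1)) stop("leak_tol must be in (0, 1)")
  n_states <- prod(bounds + 1)
  if (n_states > 20000)
    stop("FSP truncation too large (", n_states, " states; limit 20000)")
  structure(list(bounds = bounds, leak_tol = leak_tol, n_states = n_states),
            class = "lfns_fspconfig")
}

# Enumerate the truncated state space (n_states x n_x, mixed-radix order)
# and the index map x -> row.
fsp_states <- function(bounds) {
  grids <- lapply(bounds, function(b) 0:b)
  S <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  dimnames(S) <- NULL
  storage.mode(S) <- "integer"
  S
}

fsp_state_index <- function(S, bounds) {
  radix <- cumprod(c(1, bounds[-length(bounds)] + 1))
  drop(S %*% radix) + 1L
}

# Truncated CME generator Q (n_s x n_s, sparse): dp/dt = t(Q) %*% p.
# Transitions leaving the truncation contribute only to the diagonal, so
# their probability mass leaks out of the system (standard FSP).
fsp_generator <- function(network, theta, cfg) {
  S <- fsp_states(cfg$bounds)
  n_s <- nrow(S)
  rates <- rates_from_theta(network, theta)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_out <- numeric(n_s)
  for (j in seq_len(network$n_R)) {
    a <- rep(rates[j], n_s)
    for (i in seq_len(network$n_x)) {
      p <- network$Pre[j, i]
      if (p > 0) a <- a * choose(S[, i], p)
    }
    nz <- which(a > 0)
    if (length(nz) == 0) next
    target <- sweep(S[nz, , drop = FALSE], 2, network$Stoich[j, ], "+")
    inside <- rowSums(target < 0) == 0 &
      rowSums(sweep(target, 2, cfg$bounds, ">")) == 0
    diag_out[nz] <- diag_out[nz] + a[nz]
    keep <- nz[inside]
    if (length(keep)) {
      ii <- c(ii, keep)
      jj <- c(jj, fsp_state_index(target[inside, , drop = FALSE], cfg$bounds))
      vv <- c(vv, a[keep])
    }
  }
  Q <- Matrix::sparseMatrix(i = c(ii, seq_len(n_s)), j = c(jj, seq_len(n_s)),
                            x = c(vv, -diag_out), dims = c(n_s, n_s))
  list(Q = Q, S = S)
}

#' Exact (finite-state-projection) log-likelihood
#'
#' Computes the log-likelihood of a parameter vector for time-series data
#' by filtering on the truncated chemical master equation: the probability
#' vector is propagated between observation times with the matrix
#' exponential of the truncated generator, multiplied pointwise by the
#' observation density, and the log normalizing constants accumulate into
#' the log-likelihood. Trajectories are independent, so their
#' log-likelihoods add. Deterministic: repeated calls are bit-identical.
#'
#' @inheritParams pf_loglikelihood
#' @param cfg an \code{lfns_fspconfig}; the tracked probability leak out of
#'   the truncation must stay below \code{cfg$leak_tol}, otherwise an error
#'   asks for a larger truncation.
#' @param on_leak \code{"error"} (default) to fail on excess leak, or
#'   \code{"value"} to return the (lower-bound) likelihood regardless, with
#'   the accumulated leak attached as attribute \code{"leak"}. The latter
#'   is used by the evidence quadrature, which instead verifies that leaky
#'   grid points contribute negligibly to the integral.
#' @return log-likelihood value with attribute \code{"leak"}.
#' @export
fsp_loglikelihood <- function(network, obs, theta, data, cfg, t0 = 0,
                              on_leak = c("error", "value")) {
  on_leak <- match.arg(on_leak)
  stopifnot(inherits(cfg, "lfns_fspconfig"))
  gen <- fsp_generator(network, theta, cfg)
  Qt <- Matrix::t(gen$Q)
  mu <- gen$S %*% t(obs$C)  # n_s x n_y channel means per state
  # cache the propagator per distinct inter-observation interval
  prop_cache <- list()
  propagator <- function(dt) {
    key <- sprintf("%.15g", dt)
    if (is.null(prop_cache[[key]]))
      prop_cache[[key]] <<- as.matrix(Matrix::expm(Qt * dt))
    prop_cache[[key]]
  }
  x0ix <- fsp_state_index(matrix(network$x0, nrow = 1), cfg$bounds)
  if (any(network$x0 > cfg$bounds))
    stop("initial state outside FSP truncation")
  total <- 0; leak <- 0
  for (m in seq_len(data$M)) {
    tt <- data$times[[m]]; Y <- data$y[[m]]
    p <- numeric(cfg$n_states); p[x0ix] <- 1
    t_prev <- t0
    for (tau in seq_along(tt)) {
      dt <- tt[tau] - t_prev
      if (dt > 0) p <- drop(propagator(dt) %*% p)
      p[p < 0] <- 0  # clip matrix-exponential round-off
      leak <- leak + max(0, 1 - sum(p))
      g <- rep(1, cfg$n_states)
      for (c in seq_len(obs$n_y))
        g <- g * stats::dnorm(Y[tau, c], mean = mu[, c], sd = obs$sigma[c])
      p <- p * g
      norm <- sum(p)
      if (norm <= 0) return(structure(-Inf, leak = leak))
      total <- total + log(norm)
      p <- p / norm
      t_prev <- tt[tau]
    }
  }
  if (on_leak == "error" && leak > cfg$leak_tol)
    stop(sprintf("FSP probability leak %.3g exceeds tolerance %.3g; enlarge the truncation",
                 leak, cfg$leak_tol))
  structure(total, leak = leak)
}

#' Grid quadrature of the Bayesian evidence (oracle)
#'
#' Deterministic ground-truth evidence for models with one or two inferred
#' parameters: the FSP likelihood is evaluated on a grid and integrated
#' against the prior by the trapezoidal rule in the prior's transformed
#' coordinates (log-scale for log-uniform dimensions, where the prior
#' density is constant).
#'
#' @inheritParams fsp_loglikelihood
#' @param prior an \code{lfns_prior} (1 or 2 dimensions).
#' @param grid numeric vector of parameter values (1-D), or a list of two
#'   such vectors (2-D tensor grid). Values in the original parameter
#'   scale, spanning the prior box.
#' @return list with \code{logZ}, \code{Z}, \code{grid} and the matrix/vector
#'   of \code{loglik} values on the grid.
#' @export
grid_evidence <- function(network, obs, prior, data, grid, cfg, t0 = 0) {
  if (prior$d > 2) stop("grid oracle supports at most 2 inferred parameters")
  tb <- prior_transform_bounds(prior)
  log_prior_z <- -sum(log(tb$upper - tb$lower))  # uniform in transformed space
  if (prior$d == 1) {
    g <- sort(as.numeric(if (is.list(grid)) grid[[1]] else grid))
    evals <- lapply(g, function(th)
      fsp_loglikelihood(network, obs, th, data, cfg, t0, on_leak = "value"))
    ll <- vapply(evals, as.numeric, numeric(1))
    leak <- vapply(evals, attr, numeric(1), "leak")
    z <- drop(prior_transform(prior, matrix(g, ncol = 1)))
    logZ <- log_trapezoid(z, ll + log_prior_z)
    check_leaky_contribution(z, ll + log_prior_z, leak > cfg$leak_tol, logZ)
    return(list(logZ = logZ, Z = exp(logZ), grid = g, loglik = ll,
                leak = leak))
  }
  g1 <- sort(as.numeric(grid[[1]])); g2 <- sort(as.numeric(grid[[2]]))
  ll <- matrix(NA_real_, length(g1), length(g2))
  leaky <- matrix(FALSE, length(g1), length(g2))
  for (i in seq_along(g1)) for (j in seq_along(g2)) {
    e <- fsp_loglikelihood(network, obs, c(g1[i], g2[j]), data, cfg, t0,
                           on_leak = "value")
    ll[i, j] <- as.numeric(e)
    leaky[i, j] <- attr(e, "leak") > cfg$leak_tol
  }
  z1 <- drop(prior_transform(prior, cbind(g1, min(g2)))[, 1])
  z2 <- drop(prior_transform(prior, cbind(min(g1), g2))[, 2])
  # iterated trapezoid over the tensor grid, in the log domain
  inner <- vapply(seq_along(g1), function(i)
    log_trapezoid(z2, ll[i, ] + log_prior_z), numeric(1))
  logZ <- log_trapezoid(z1, inner)
  if (any(leaky)) {
    panel <- outer(c(diff(z1) / 2, 0) + c(0, diff(z1) / 2),
                   c(diff(z2) / 2, 0) + c(0, diff(z2) / 2))
    contrib <- logsumexp(ll[leaky] + log_prior_z + log(panel[leaky]))
    if (contrib > logZ + log(1e-6))
      stop("grid points with excess FSP leak contribute non-negligibly to the evidence; enlarge the truncation")
  }
  list(logZ = logZ, Z = exp(logZ), grid = list(g1, g2), loglik = ll)
}

# The truncated-CME likelihood is a lower bound wherever probability mass
# leaks; quadrature stays trustworthy only if those grid points carry a
# negligible share of the integral.
check_leaky_contribution <- function(z, logf, leaky, logZ) {
  if (!any(leaky)) return(invisible())
  dz <- c(diff(z) / 2, 0) + c(0, diff(z) / 2)
  vals <- logf[leaky] + log(dz[leaky])
  vals <- vals[is.finite(vals)]
  if (length(vals) && logsumexp(vals) > logZ + log(1e-6))
    stop("grid points with excess FSP leak contribute non-negligibly to the evidence; enlarge the truncation")
  invisible()
}

#' Grid posterior density (oracle)
#'
#' Pointwise prior-times-likelihood normalized by the grid evidence, for a
#' single inferred parameter. The returned density is with respect to the
#' transformed coordinate \code{z} (\code{log(theta)} for a log-uniform
#' prior), in which it integrates to 1 by the trapezoidal rule.
#'
#' @inheritParams grid_evidence
#' @return data.frame with columns \code{theta}, \code{z}, \code{loglik}
#'   and \code{density} (w.r.t. \code{z}).
#' @export
grid_posterior <- function(network, obs, prior, data, grid, cfg, t0 = 0) {
  if (prior$d != 1) stop("grid_posterior supports exactly 1 inferred parameter")
  ev <- grid_evidence(network, obs, prior, data, grid, cfg, t0)
  tb <- prior_transform_bounds(prior)
  z <- drop(prior_transform(prior, matrix(ev$grid, ncol = 1)))
  logdens <- ev$loglik - log(tb$upper - tb$lower) - ev$logZ
  data.frame(theta = ev$grid, z = z, loglik = ev$loglik,
             density = exp(logdens))
}

# log of the trapezoidal integral of exp(logf) over ordered abscissae x.
log_trapezoid <- function(x, logf) {
  stopifnot(length(x) == length(logf), length(x) >= 2)
  n <- length(x)
  hi <- pmax(logf[-n], logf[-1])
  gap <- abs(logf[-n] - logf[-1])
  gap[!is.finite(gap)] <- Inf  # one or both endpoints at -Inf
  panel <- log(diff(x) / 2) + hi + log1p(exp(-gap))
  panel[!is.finite(hi)] <- -Inf
  logsumexp(panel)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}
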