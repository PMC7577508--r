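# Constrained-prior proposal machinery.
#
# All fitting and sampling happens in the prior's transformed space z
# (log-scale for log-uniform dimensions), where the prior is uniform on a
# box.  "Sample from the prior restricted to the support of the live-point
# density estimate" then means: sample uniformly on {support} /\ {box}.
# For the mixture sampler this is classical rejection sampling with the
# fitted mixture rho as proposal and acceptance probability tau/rho(z)
# (tau = the support threshold), which is exactly uniform on {rho >= tau};
# for the ellipsoid sampler candidates are uniform in the ellipsoid by
# construction.  Mixture fits poorly across decades on the linear scale,
# which is why the log-transform matters.

#' Fit a proposal model to the live points
#'
#' Estimates the region of parameter space occupied by the current live
#' set, from which replacement candidates are drawn with the prior's law
#' restricted to that region.
#'
#' Kinds: \code{"prior"} (whole prior box; no fit), \code{"gmm"} (Gaussian
#' mixture fitted to the transformed live points, component count chosen
#' by BIC up to \code{min(N, 20)}; the support is the super-level set of
#' the mixture density at threshold \code{tau} = 0.9 times the lowest
#' mixture density over the live points, so every live point is inside;
#' \code{"dpgmm"} is accepted as an alias), and \code{"ellipsoid"}
#' (covariance-shaped ellipsoid covering all live points, radius inflated
#' by \code{inflate}). Degenerate live sets (all points nearly identical)
#' are handled by flooring the covariance at \code{1e-6} times the squared
#' box width per dimension, never by failing.
#'
#' @param live_thetas numeric matrix (rows = live points, original
#'   parameter scale) or vector for d = 1.
#' @param kind \code{"prior"}, \code{"gmm"} (alias \code{"dpgmm"}) or
#'   \code{"ellipsoid"}.
#' @param prior an \code{lfns_prior}.
#' @param inflate ellipsoid radius inflation factor (default 1.5).
#' @param max_components cap on mixture components.
#' @return an object of class \code{lfns_proposal}.
#' @export
fit_proposal <- function(live_thetas, kind = c("gmm", "dpgmm", "ellipsoid", "prior"),
                         prior, inflate = 1.5, max_components = 20L) {
  kind <- match.arg(kind)
  if (kind == "dpgmm") kind <- "gmm"
  tb <- prior_transform_bounds(prior)
  if (kind == "prior")
    return(structure(list(kind = "prior", bounds = tb, d = prior$d),
                     class = "lfns_proposal"))
  Z <- prior_transform(prior, as_theta_matrix(live_thetas, prior$d))
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = prior$d)
  if (nrow(Z) < 2) stop("need at least 2 live points to fit a proposal")
  var_floor <- 1e-6 * (tb$upper - tb$lower)^2

  if (kind == "ellipsoid") {
    ctr <- colMeans(Z)
    S <- stats::cov(Z)
    if (prior$d == 1) S <- matrix(S, 1, 1)
    diag(S) <- pmax(diag(S), var_floor)
    L <- t(chol(S))
    dev <- t(Z) - ctr
    y <- forwardsolve(L, dev)
    r2 <- max(colSums(y^2))
    mod <- list(kind = "ellipsoid", bounds = tb, d = prior$d,
                center = ctr, L = L, radius = inflate * sqrt(max(r2, 1e-12)))
    return(structure(mod, class = "lfns_proposal"))
  }

  # Gaussian mixture (BIC-selected component count)
  G <- seq_len(max(1L, min(nrow(Z) - 1L, max_components)))
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(if (prior$d == 1) drop(Z) else Z,
                                    G = G, verbose = FALSE)),
    error = function(e) NULL)
  mix <- if (!is.null(fit)) mclust_to_mixture(fit, prior$d) else NULL
  if (is.null(mix)) {
    # degenerate fallback: one floored Gaussian at the sample mean
    S <- stats::cov(Z); if (prior$d == 1) S <- matrix(S, 1, 1)
    S[!is.finite(S)] <- 0
    diag(S) <- pmax(diag(S), var_floor)
    mix <- list(pro = 1, mean = matrix(colMeans(Z), ncol = 1),
                sigma = array(S, c(prior$d, prior$d, 1)))
  }
  # floor tiny component variances so the density stays evaluable
  for (g in seq_along(mix$pro)) {
    Sg <- mix$sigma[, , g, drop = FALSE]
    dim(Sg) <- c(prior$d, prior$d)
    diag(Sg) <- pmax(diag(Sg), var_floor)
    mix$sigma[, , g] <- Sg
  }
  mix$chol <- lapply(seq_along(mix$pro), function(g) {
    Sg <- matrix(mix$sigma[, , g], prior$d, prior$d)
    t(chol(Sg))
  })
  dens_live <- mixture_density(mix, Z)
  mod <- list(kind = "gmm", bounds = tb, d = prior$d, mix = mix,
              tau = 0.9 * min(dens_live), n_components = length(mix$pro))
  structure(mod, class = "lfns_proposal")
}

#' @export
print.lfns_proposal <- function(x, ...) {
  extra <- switch(x$kind,
    gmm = sprintf(" (%d components, tau = %.3g)", x$n_components, x$tau),
    ellipsoid = sprintf(" (radius %.3g)", x$radius), "")
  cat(sprintf("Proposal model: %s%s, d = %d\n", x$kind, extra, x$d))
  invisible(x)
}

mclust_to_mixture <- function(fit, d) {
  p <- fit$parameters
  if (is.null(p) || is.null(p$pro)) return(NULL)
  G <- length(p$pro)
  mean <- matrix(p$mean, nrow = d)
  sigma <- array(0, c(d, d, G))
  if (d == 1) {
    s2 <- p$variance$sigmasq
    if (length(s2) == 1) s2 <- rep(s2, G)
    for (g in seq_len(G)) sigma[, , g] <- s2[g]
  } else {
    sg <- p$variance$sigma
    if (is.null(sg)) return(NULL)
    for (g in seq_len(G))
      sigma[, , g] <- if (length(dim(sg)) == 3) sg[, , g] else sg
  }
  list(pro = p$pro / sum(p$pro), mean = mean, sigma = sigma)
}

# density of the fitted mixture at rows of Z (uses the cached Cholesky
# factors when present)
mixture_density <- function(mix, Z) {
  Z <- if (is.matrix(Z)) Z else matrix(Z, ncol = nrow(mix$mean))
  d <- ncol(Z)
  dens <- numeric(nrow(Z))
  for (g in seq_along(mix$pro)) {
    L <- if (!is.null(mix$chol)) mix$chol[[g]] else
      t(chol(matrix(mix$sigma[, , g], d, d)))
    dev <- t(Z) - mix$mean[, g]
    y <- forwardsolve(L, dev)
    logdet <- 2 * sum(log(diag(L)))
    lg <- -0.5 * (colSums(y^2) + logdet + d * log(2 * pi))
    dens <- dens + mix$pro[g] * exp(lg)
  }
  dens
}

mixture_draw <- function(mix, n) {
  d <- nrow(mix$mean)
  comp <- sample.int(length(mix$pro), n, replace = TRUE, prob = mix$pro)
  out <- matrix(0, n, d)
  for (g in unique(comp)) {
    idx <- which(comp == g)
    L <- mix$chol[[g]]
    out[idx, ] <- t(mix$mean[, g] + L %*%
                      matrix(stats::rnorm(d * length(idx)), d))
  }
  out
}

#' Draw from the prior restricted to the proposal support
#'
#' Returns a parameter vector whose law is the prior restricted to the
#' fitted proposal's support. Candidates come from the fitted mixture
#' (accepted with probability \code{tau / rho(z)}, which makes accepted
#' draws exactly uniform on the support in the transformed space where the
#' prior is uniform), from the ellipsoid (uniform by construction), or
#' from the prior itself; candidates outside the prior box are rejected.
#'
#' @param model an \code{lfns_proposal}.
#' @param prior the \code{lfns_prior} the model was fitted under.
#' @param max_attempts rejection budget before giving up.
#' @return list with \code{theta} (parameter vector, original scale) and
#'   \code{attempts} (candidates consumed).
#' @export
sample_support_uniform_prior <- function(model, prior, max_attempts = 1e6) {
  stopifnot(inherits(model, "lfns_proposal"))
  tb <- model$bounds
  in_box <- function(z) all(z >= tb$lower) && all(z <= tb$upper)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("proposal sampler exhausted its rejection budget; ",
           "consider a different sampler kind or a larger support threshold")
    if (model$kind == "prior") {
      th <- sample_prior(prior)
      return(list(theta = th, attempts = attempts))
    } else if (model$kind == "ellipsoid") {
      g <- stats::rnorm(model$d)
      u <- stats::runif(1)^(1 / model$d)
      y <- g / sqrt(sum(g^2)) * u * model$radius
      z <- model$center + drop(model$L %*% y)
      if (!in_box(z)) next
      return(list(theta = prior_untransform(prior, z), attempts = attempts))
    } else {
      z <- drop(mixture_draw(model$mix, 1))
      if (!in_box(z)) next
      rho <- mixture_density(model$mix, matrix(z, nrow = 1))
      if (rho < model$tau) next
      if (stats::runif(1) > model$tau / rho) next
      return(list(theta = prior_untransform(prior, z), attempts = attempts))
    }
  }
}

#' Support membership of parameter vectors
#'
#' Checks which parameter vectors lie inside a fitted proposal model's
#' support (and the prior box). Useful as a coverage diagnostic for the
#' constrained-prior samplers.
#'
#' @param model an \code{lfns_proposal}.
#' @param prior the matching \code{lfns_prior}.
#' @param thetas matrix of parameter vectors (rows), original scale.
#' @return logical vector, one entry per row.
#' @export
proposal_in_support <- function(model, prior, thetas) {
  Z <- prior_transform(prior, as_theta_matrix(thetas, prior$d))
  if (!is.matrix(Z)) Z <- matrix(Z, ncol = prior$d)
  tb <- model$bounds
  inbox <- rowSums(sweep(Z, 2, tb$lower, "<")) == 0 &
    rowSums(sweep(Z, 2, tb$upper, ">")) == 0
  if (model$kind == "prior") return(inbox)
  if (model$kind == "ellipsoid") {
    y <- forwardsolve(model$L, t(Z) - model$center)
    return(inbox & colSums(y^2) <= model$radius^2 + 1e-12)
  }
  inbox & mixture_density(model$mix, Z) >= model$tau * (1 - 1e-12)
}

as_theta_matrix <- function(thetas, d) {
  if (is.matrix(thetas)) thetas else matrix(thetas, ncol = d)
}
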