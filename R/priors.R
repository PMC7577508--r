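#' Box prior specification
#'
#' Defines an independent product prior over the inferred parameters. Each
#' dimension is either uniform on \code{[lower, upper]} or log-uniform
#' (uniform in \code{log(theta)}) on the same interval. These are the two
#' prior families used throughout stochastic reaction-network inference,
#' where rate constants typically range over several decades.
#'
#' @param name character vector of parameter names.
#' @param kind character vector, each entry \code{"uniform"} or
#'   \code{"log-uniform"}.
#' @param lower,upper numeric bounds; \code{lower < upper}, and
#'   \code{lower > 0} for log-uniform dimensions.
#' @return an object of class \code{lfns_prior}.
#' @export
prior_spec <- function(name, kind, lower, upper) {
  d <- length(name)
  kind <- rep_len(kind, d)
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (anyDuplicated(name)) stop("duplicate parameter names in prior")
  if (!all(kind %in% c("uniform", "log-uniform")))
    stop("prior kind must be 'uniform' or 'log-uniform'")
  if (any(!(lower < upper)))
    stop("prior requires lower < upper in every dimension")
  if (any(kind == "log-uniform" & lower <= 0))
    stop("log-uniform prior requires lower > 0")
  structure(
    list(name = as.character(name), kind = kind, lower = lower, upper = upper, d = d),
    class = "lfns_prior"
  )
}

#' @export
print.lfns_prior <- function(x, ...) {
  cat(sprintf("Prior over %d parameter(s):\n", x$d))
  for (k in seq_len(x$d))
    cat(sprintf("  %-12s %-11s [%g, %g]\n", x$name[k], x$kind[k], x$lower[k], x$upper[k]))
  invisible(x)
}

#' Log prior density
#'
#' Evaluates the log density of a box prior at a parameter vector. Outside
#' the box the value is \code{-Inf}; inside it is the sum of per-dimension
#' log densities: \code{-log(upper - lower)} for a uniform dimension and
#' \code{-log(theta) - log(log(upper/lower))} for a log-uniform one.
#'
#' @param prior an \code{lfns_prior}.
#' @param theta numeric vector of length \code{prior$d}.
#' @return a single number, possibly \code{-Inf}.
#' @export
prior_logdensity <- function(prior, theta) {
  stopifnot(inherits(prior, "lfns_prior"), length(theta) == prior$d)
  if (any(!is.finite(theta)) || any(theta < prior$lower) || any(theta > prior$upper))
    return(-Inf)
  unif <- prior$kind == "uniform"
  val <- 0
  if (any(unif))
    val <- val - sum(log(prior$upper[unif] - prior$lower[unif]))
  if (any(!unif))
    val <- val - sum(log(theta[!unif])) -
      sum(log(log(prior$upper[!unif] / prior$lower[!unif])))
  val
}

#' Draw from the prior
#'
#' @param prior an \code{lfns_prior}.
#' @param n number of draws.
#' @return an \code{n x d} numeric matrix with parameter names as columns
#'   (a plain vector if \code{n == 1} and \code{drop = TRUE}).
#' @param drop if \code{TRUE} and \code{n == 1}, return a bare vector.
#' @export
sample_prior <- function(prior, n = 1L, drop = TRUE) {
  stopifnot(inherits(prior, "lfns_prior"))
  z <- matrix(stats::runif(n * prior$d), nrow = n)
  lo <- prior_transform_bounds(prior)$lower
  up <- prior_transform_bounds(prior)$upper
  zz <- sweep(sweep(z, 2, up - lo, "*"), 2, lo, "+")
  th <- prior_untransform(prior, zz)
  colnames(th) <- prior$name
  if (n == 1L && drop) drop(th) else th
}

# Transformed ("sampling") space: identity for uniform dims, log for
# log-uniform dims.  The prior is uniform on a box in this space, which is
# what the constrained-prior rejection samplers exploit.
prior_transform_bounds <- function(prior) {
  lo <- prior$lower; up <- prior$upper
  lg <- prior$kind == "log-uniform"
  lo[lg] <- log(lo[lg]); up[lg] <- log(up[lg])
  list(lower = lo, upper = up)
}

prior_transform <- function(prior, theta) {
  th <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  lg <- prior$kind == "log-uniform"
  th[, lg] <- log(th[, lg])
  if (is.matrix(theta)) th else drop(th)
}

prior_untransform <- function(prior, z) {
  zz <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  lg <- prior$kind == "log-uniform"
  zz[, lg] <- exp(zz[, lg])
  if (is.matrix(z)) zz else drop(zz)
}
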