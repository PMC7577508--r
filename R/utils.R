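#' @keywords internal
#' @useDynLib lfns, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' 1-Wasserstein distance between two 1-D distributions
#'
#' Computes \eqn{W_1 = \int |F_1(x) - F_2(x)| dx} between two univariate
#' distributions, each given either as a weighted sample
#' (\code{list(x = values, w = weights)}) or as a density on a grid
#' (\code{list(x = grid, density = values)}, integrated to a CDF by the
#' trapezoidal rule). Used to compare a weighted nested-sampling posterior
#' with a grid oracle posterior, typically on the log10-parameter scale.
#'
#' @param a,b distribution specifications as above.
#' @return a non-negative number in the units of \code{x}.
#' @export
wasserstein1 <- function(a, b) {
  cdf_fun <- function(spec) {
    if (!is.null(spec$density)) {
      x <- spec$x
      o <- order(x); x <- x[o]; dens <- spec$density[o]
      cum <- c(0, cumsum(diff(x) * (dens[-1] + dens[-length(dens)]) / 2))
      cum <- cum / cum[length(cum)]
      stats::approxfun(x, cum, method = "linear", yleft = 0, yright = 1)
    } else {
      x <- spec$x
      w <- if (is.null(spec$w)) rep(1 / length(x), length(x)) else spec$w
      o <- order(x)
      x <- x[o]; w <- w[o] / sum(w)
      cum <- cumsum(w)
      stats::approxfun(x, cum, method = "constant", yleft = 0, yright = 1,
                       f = 0, ties = "ordered")
    }
  }
  Fa <- cdf_fun(a); Fb <- cdf_fun(b)
  xs <- sort(unique(c(a$x, b$x)))
  # refine between knots so piecewise-linear/constant segments integrate well
  grid <- sort(unique(c(xs, seq(min(xs), max(xs), length.out = 2048))))
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  sum(abs(Fa(mid) - Fb(mid)) * diff(grid))
}
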