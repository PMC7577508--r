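#' Mass-action reaction network
#'
#' A chemical reaction network over \code{n_x} species and \code{n_R}
#' reactions \eqn{R_j: \sum_i p_{ji} X_i \to \sum_i q_{ji} X_i} with
#' mass-action propensities \eqn{a_j(x) = c_j \prod_i {x_i \choose p_{ji}}}
#' (number of distinct reactant multisets, the standard CME convention).
#' Each reaction rate \eqn{c_j} is either one of the inferred parameters
#' (given by name) or a fixed literal.
#'
#' @param species character vector of species names.
#' @param reactants,products list of length \code{n_R}; each element an
#'   integer vector of length \code{n_x} of molecule counts (non-negative).
#' @param rates list of length \code{n_R}; each element either a parameter
#'   name (character) or a fixed numeric rate.
#' @param x0 integer initial state (defaults to all zeros).
#' @param par_names character vector of inferred parameter names, in the
#'   order of the parameter vector \code{theta}.
#' @return an object of class \code{lfns_network}.
#' @export
reaction_network <- function(species, reactants, products, rates,
                             par_names = character(), x0 = NULL) {
  n_x <- length(species)
  n_R <- length(reactants)
  if (length(products) != n_R || length(rates) != n_R)
    stop("reactants, products and rates must have one entry per reaction")
  as_count_mat <- function(lst, what) {
    if (n_R == 0) return(matrix(0L, nrow = 0, ncol = n_x))
    m <- do.call(rbind, lapply(lst, function(v) {
      if (length(v) != n_x) stop(sprintf("%s vector of wrong length", what))
      v
    }))
    if (any(m < 0) || any(m != round(m)))
      stop(sprintf("%s counts must be non-negative integers", what))
    storage.mode(m) <- "integer"
    m
  }
  Pre <- as_count_mat(reactants, "reactant")
  Post <- as_count_mat(products, "product")
  rate_ix <- integer(n_R); rate_fixed <- rep(NA_real_, n_R)
  for (j in seq_len(n_R)) {
    r <- rates[[j]]
    if (is.character(r)) {
      ix <- match(r, par_names)
      if (is.na(ix))
        stop(sprintf("reaction %d refers to unknown parameter '%s'", j, r))
      rate_ix[j] <- ix
    } else if (is.numeric(r) && length(r) == 1 && is.finite(r) && r >= 0) {
      rate_ix[j] <- NA_integer_; rate_fixed[j] <- r
    } else stop(sprintf("rate of reaction %d must be a parameter name or a non-negative number", j))
  }
  if (is.null(x0)) x0 <- rep(0L, n_x)
  if (length(x0) != n_x || any(x0 < 0) || any(x0 != round(x0)))
    stop("x0 must be a non-negative integer state of length n_x")
  structure(
    list(species = as.character(species), n_x = n_x, n_R = n_R,
         Pre = Pre, Post = Post, Stoich = Post - Pre,
         rate_ix = rate_ix, rate_fixed = rate_fixed,
         par_names = as.character(par_names), x0 = as.integer(x0)),
    class = "lfns_network"
  )
}

#' @export
print.lfns_network <- function(x, ...) {
  cat(sprintf("Reaction network: %d species, %d reactions, %d inferred parameter(s)\n",
              x$n_x, x$n_R, length(x$par_names)))
  invisible(x)
}

# Numeric rate constants c_j for a given parameter vector theta.
rates_from_theta <- function(network, theta) {
  if (length(theta) != length(network$par_names))
    stop("theta has wrong length for this network")
  r <- network$rate_fixed
  free <- !is.na(network$rate_ix)
  r[free] <- theta[network$rate_ix[free]]
  r
}

#' Linear Gaussian observation model
#'
#' Observed channels are linear combinations (non-negative integer
#' coefficients) of the species counts with additive Gaussian noise:
#' \eqn{y \sim N(C x, \mathrm{diag}(\sigma^2))}.
#'
#' @param C numeric matrix, \code{n_y x n_x}, non-negative integer entries.
#' @param sigma numeric vector of per-channel noise standard deviations
#'   (strictly positive).
#' @param channel_names optional channel names.
#' @return an object of class \code{lfns_obsmodel}.
#' @export
observation_model <- function(C, sigma, channel_names = NULL) {
  C <- as.matrix(C)
  if (any(C < 0) || any(C != round(C)))
    stop("observation coefficients must be non-negative integers")
  sigma <- rep_len(as.numeric(sigma), nrow(C))
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("observation noise sigma must be finite and > 0")
  if (is.null(channel_names)) channel_names <- paste0("y", seq_len(nrow(C)))
  structure(list(C = C, sigma = sigma, n_y = nrow(C),
                 channel_names = channel_names),
            class = "lfns_obsmodel")
}

# log p(y | x) for a single observation vector y and one state x.
obs_logdensity <- function(obs, y, x) {
  mu <- drop(obs$C %*% x)
  sum(stats::dnorm(y, mean = mu, sd = obs$sigma, log = TRUE))
}

#' Load a model configuration file
#'
#' Reads a YAML model file holding the reaction network, observation model
#' and priors (see the shipped example configurations under
#' \code{system.file("extdata", package = "lfns")} for the schema: top-level
#' keys \code{species}, \code{x0}, \code{reactions} (each with
#' \code{reactants}/\code{products} maps and a \code{rate} that is a
#' parameter name or number), \code{parameters} (entries either
#' \code{\{name, kind, lower, upper\}} or \code{\{name, fixed\}} — fixed
#' entries are substituted into the rates), and \code{observation} with a
#' list of \code{channels} (\code{species} map and noise \code{sigma}).
#'
#' @param config_path path to a YAML file.
#' @return a list with elements \code{network} (\code{lfns_network}),
#'   \code{obs} (\code{lfns_obsmodel}) and \code{prior} (\code{lfns_prior}).
#' @export
load_model <- function(config_path) {
  if (!file.exists(config_path)) stop("model config not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  for (f in c("species", "reactions", "parameters", "observation"))
    if (is.null(cfg[[f]])) stop("model config is missing field '", f, "'")
  species <- as.character(cfg$species)
  n_x <- length(species)

  pars <- cfg$parameters
  fixed <- vapply(pars, function(p) !is.null(p$fixed), logical(1))
  fixed_vals <- stats::setNames(
    vapply(pars[fixed], function(p) as.numeric(p$fixed), numeric(1)),
    vapply(pars[fixed], function(p) as.character(p$name), character(1)))
  free_pars <- pars[!fixed]
  for (p in free_pars)
    for (f in c("name", "kind", "lower", "upper"))
      if (is.null(p[[f]])) stop("prior entry is missing field '", f, "'")
  prior <- prior_spec(
    name  = vapply(free_pars, function(p) as.character(p$name), character(1)),
    kind  = vapply(free_pars, function(p) as.character(p$kind), character(1)),
    lower = vapply(free_pars, function(p) as.numeric(p$lower), numeric(1)),
    upper = vapply(free_pars, function(p) as.numeric(p$upper), numeric(1)))

  count_vec <- function(map, where) {
    v <- rep(0L, n_x)
    if (length(map) == 0) return(v)
    ix <- match(names(map), species)
    if (anyNA(ix))
      stop("unknown species '", names(map)[is.na(ix)][1], "' in ", where)
    cnt <- as.numeric(unlist(map))
    if (any(cnt < 0) || any(cnt != round(cnt)))
      stop("negative or non-integer stoichiometry in ", where)
    v[ix] <- as.integer(cnt)
    v
  }
  reactants <- lapply(seq_along(cfg$reactions), function(j)
    count_vec(cfg$reactions[[j]]$reactants, sprintf("reaction %d reactants", j)))
  products <- lapply(seq_along(cfg$reactions), function(j)
    count_vec(cfg$reactions[[j]]$products, sprintf("reaction %d products", j)))
  rates <- lapply(cfg$reactions, function(r) {
    if (is.null(r$rate)) stop("reaction is missing field 'rate'")
    if (is.character(r$rate) && r$rate %in% names(fixed_vals))
      unname(fixed_vals[r$rate]) else r$rate
  })

  chans <- cfg$observation$channels
  if (is.null(chans) || length(chans) == 0)
    stop("observation config needs at least one channel")
  C <- do.call(rbind, lapply(seq_along(chans), function(i)
    count_vec(chans[[i]]$species, sprintf("observation channel %d", i))))
  sigma <- vapply(chans, function(ch) {
    if (is.null(ch$sigma)) stop("observation channel is missing field 'sigma'")
    as.numeric(ch$sigma)
  }, numeric(1))

  x0 <- if (is.null(cfg$x0)) NULL else as.integer(cfg$x0)
  network <- reaction_network(species, reactants, products, rates,
                              par_names = prior$name, x0 = x0)
  list(network = network, obs = observation_model(C, sigma), prior = prior)
}
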