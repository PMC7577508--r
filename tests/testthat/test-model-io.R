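test_that("prior log-density matches closed forms and normalizes", {
  p2 <- prior_spec(c("a", "b"), "uniform", 0, 1)
  expect_identical(prior_logdensity(p2, c(0.3, 0.7)), 0)
  expect_identical(prior_logdensity(p2, c(1.2, 0.5)), -Inf)
  expect_identical(prior_logdensity(p2, c(-0.1, 0.5)), -Inf)

  plog <- prior_spec("k", "log-uniform", 0.01, 100)
  expect_equal(prior_logdensity(plog, 1), -log(1 * log(1e4)))
  # normalization by quadrature, per dimension
  for (pr in list(prior_spec("x", "uniform", -2, 5), plog)) {
    mass <- integrate(function(t)
      vapply(t, function(ti) exp(prior_logdensity(pr, ti)), numeric(1)),
      pr$lower, pr$upper, rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
  }
})

test_that("prior sampling matches the prior law", {
  set.seed(101)
  pu <- prior_spec("u", "uniform", 0, 1)
  x <- sample_prior(pu, 1e5)
  expect_lt(abs(mean(x) - 0.5), 3 / sqrt(12 * 1e5))

  plog <- prior_spec("k", "log-uniform", 0.01, 100)
  y <- sample_prior(plog, 5000)
  expect_true(all(y >= 0.01 & y <= 100))
  ks <- suppressWarnings(ks.test(log(y), "punif", log(0.01), log(100)))
  expect_gt(ks$p.value, 0.01)

  # sampler/density consistency: E_pi[1 / pi(theta)] equals the box volume
  pr <- prior_spec(c("a", "k"), c("uniform", "log-uniform"), c(0, 0.1), c(2, 10))
  th <- sample_prior(pr, 5000, drop = FALSE)
  ld <- apply(th, 1, function(t) prior_logdensity(pr, t))
  expect_equal(mean(exp(-ld)), 2 * (10 - 0.1), tolerance = 0.05)

  # determinism under a fixed seed
  set.seed(5); a <- sample_prior(pr, 10, drop = FALSE)
  set.seed(5); b <- sample_prior(pr, 10, drop = FALSE)
  expect_identical(a, b)
})

test_that("model configs load with the expected structure", {
  bd <- load_model(system.file("extdata", "birth_death.yaml", package = "lfns"))
  expect_s3_class(bd$network, "lfns_network")
  expect_equal(bd$network$n_x, 1)
  expect_equal(bd$network$n_R, 2)
  expect_equal(bd$prior$d, 1)            # gamma is fixed
  expect_equal(rates_from_theta(bd$network, 1), c(1, 0.1))

  tr <- load_model(system.file("extdata", "transcription.yaml", package = "lfns"))
  expect_equal(tr$network$n_x, 11)       # 2 gene states + 8 stages + sink
  expect_equal(tr$network$n_R, 12)
  expect_equal(tr$prior$d, 4)
  expect_equal(sum(tr$obs$C), 8)         # observes the sum of the 8 stages

  # zero reactions is a valid degenerate network
  empty <- reaction_network("X", list(), list(), list(), par_names = "k")
  expect_equal(empty$n_R, 0)

  # schema violations name the offending field
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("species: [X]",
               "reactions:",
               "  - {reactants: {X: -1}, products: {}, rate: 1}",
               "parameters:",
               "  - {name: k, kind: uniform, lower: 0, upper: 1}",
               "observation:",
               "  channels:",
               "    - {species: {X: 1}, sigma: 1}"), bad)
  expect_error(load_model(bad), "stoichiometry")
})

test_that("time-series CSV round-trips and validates", {
  d1 <- timeseries_data(list(c(0.5, 1, 2)), list(matrix(c(1, 2, 3))))
  expect_equal(d1$M, 1)
  expect_equal(length(d1$times[[1]]), 3)

  set.seed(3)
  times <- replicate(5, sort(runif(4)) + (0:3) * 0, simplify = FALSE)
  y <- lapply(1:5, function(i) matrix(rnorm(8), 4, 2))
  d5 <- timeseries_data(times, y)
  f <- tempfile(fileext = ".csv")
  write_timeseries(d5, f)
  back <- read_timeseries(f)
  expect_equal(back$M, 5)
  expect_equal(back$times, d5$times)
  expect_equal(back$y, d5$y)

  # duplicated timepoint is rejected
  writeLines(c("trajectory,time,y1", "1,1,0.5", "1,1,0.7"), f)
  expect_error(read_timeseries(f), "duplicated timepoint")
  expect_error(timeseries_data(list(c(2, 1)), list(matrix(c(1, 2)))),
               "strictly increasing")
})
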