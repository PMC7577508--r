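test_that("live-set initialization samples the joint prior", {
  # constant mock estimator: every particle carries the same value
  l2 <- initialize_live(list(prior = prior_spec("a", "uniform", 0, 1)),
                        dummy_data, N = 2, loglik_fn = function(th) 0)
  expect_equal(l2$loglik, c(0, 0))

  # theta marginal is the prior (KS against the log-uniform law)
  m <- list(prior = prior_spec("k", "log-uniform", 0.01, 100))
  set.seed(51)
  lv <- initialize_live(m, dummy_data, N = 400,
                        loglik_fn = function(th) rnorm(1))
  ks <- suppressWarnings(ks.test(log(lv$theta[, 1]), "punif",
                                 log(0.01), log(100)))
  expect_gt(ks$p.value, 0.01)
  expect_error(initialize_live(m, dummy_data, N = 1, loglik_fn = function(th) 0),
               "at least 2")
})

test_that("one step preserves the ordering contract", {
  m <- list(prior = prior_spec("a", "uniform", 0, 1))
  # deterministic likelihood theta -> theta: after a step every live point
  # exceeds the dead threshold
  set.seed(52)
  lv <- initialize_live(m, dummy_data, N = 10, loglik_fn = function(th) th[1])
  st <- lfns_step(lv, m, dummy_data, r = 1, sampler = "prior",
                  loglik_fn = function(th) th[1])
  expect_true(all(st$live$loglik > st$dead$loglik))
  expect_equal(st$dead$live_count, 10L)
  expect_equal(st$live$N, 10)
  # batch removal records live counts N, N-1, ..., N-r+1
  st3 <- lfns_step(lv, m, dummy_data, r = 3, sampler = "prior",
                   loglik_fn = function(th) th[1])
  expect_equal(st3$dead$live_count, c(10L, 9L, 8L))
  expect_true(!is.unsorted(st3$dead$loglik))
  expect_gt(st3$acceptance, 0)
  expect_lte(st3$acceptance, 1)
})

test_that("a constant-likelihood plateau is detected, not looped forever", {
  m <- list(prior = prior_spec("a", "uniform", 0, 1))
  set.seed(53)
  lv <- initialize_live(m, dummy_data, N = 5, loglik_fn = function(th) 1.5)
  expect_error(lfns_step(lv, m, dummy_data, r = 1, sampler = "prior",
                         loglik_fn = function(th) 1.5),
               "plateau")
})

test_that("the full loop recovers an analytic Gaussian-bump evidence", {
  gb <- gauss_bump_model(mu = 0.5, s = 0.05)
  run <- run_lfns(gb$model, dummy_data, N = 100, r = 10, sampler = "gmm",
                  delta = 0.001, max_iter = 300, seed = 54,
                  loglik_fn = gb$loglik)
  expect_true(run$converged)
  sdZ <- sqrt(estimator_variance(run$evidence)$var)
  expect_lt(abs(run$evidence$Z_tot - exp(gb$logZ)), 3 * sdZ + 0.02 * exp(gb$logZ))
  pm <- weighted_mean(run$posterior$a, run$posterior$weight)
  psd <- sqrt(weighted_var(run$posterior$a, run$posterior$weight))
  expect_lt(abs(pm - gb$post_mean), 0.05 / sqrt(100) * 3 + 0.01)
  expect_lt(abs(psd - 0.05), 0.02)

  # structural invariants along the trace
  tr <- run$trace
  expect_true(!is.unsorted(tr$eps))
  expect_true(all(diff(tr$log_xhat) < 0))
  expect_true(!is.unsorted(tr$logZ_D))
  expect_true(all(exp(tr$log_var_tot) >= exp(tr$log_var_min) - 1e-18))
  expect_true(all(tr$delta_lfns >= 0))
  # the achievable and current uncertainties converge by termination
  n <- nrow(tr)
  expect_gt(exp((tr$log_var_min[n] - tr$log_var_tot[n]) / 2), 0.9)
  expect_true(all(tr$acceptance > 0 & tr$acceptance <= 1))
})

test_that("stopping immediately returns the prior-sample estimator", {
  gb <- gauss_bump_model()
  run0 <- run_lfns(gb$model, dummy_data, N = 200, r = 10, delta = 1e-9,
                   max_iter = 0, seed = 55, loglik_fn = gb$loglik)
  expect_equal(run0$evidence$m, 0)
  # Z_tot = mean live likelihood, which estimates Z itself
  expect_equal(run0$evidence$logZ_tot, run0$evidence$log_Lbar)
  expect_lt(abs(run0$evidence$Z_tot - exp(gb$logZ)),
            3 * sqrt(estimator_variance(run0$evidence)$var))
})

test_that("seeded runs are reproducible and batch sizes agree", {
  gb <- gauss_bump_model()
  a <- run_lfns(gb$model, dummy_data, N = 50, r = 5, delta = 0.01,
                max_iter = 100, seed = 56, loglik_fn = gb$loglik)
  b <- run_lfns(gb$model, dummy_data, N = 50, r = 5, delta = 0.01,
                max_iter = 100, seed = 56, loglik_fn = gb$loglik)
  expect_identical(a$evidence$logZ_tot, b$evidence$logZ_tot)
  expect_identical(a$posterior, b$posterior)

  # serial (r = 1) and batch (r = 10) runs agree within their own
  # reported uncertainties
  s1 <- run_lfns(gb$model, dummy_data, N = 50, r = 1, delta = 0.005,
                 max_iter = 400, seed = 57, loglik_fn = gb$loglik)
  s10 <- run_lfns(gb$model, dummy_data, N = 50, r = 10, delta = 0.005,
                  max_iter = 400, seed = 58, loglik_fn = gb$loglik)
  tol <- 3 * (sqrt(estimator_variance(s1$evidence)$var) +
                sqrt(estimator_variance(s10$evidence)$var))
  expect_lt(abs(s1$evidence$Z_tot - s10$evidence$Z_tot), tol + 0.02)
})

test_that("proposal kinds change efficiency, not the estimator's law", {
  gb <- gauss_bump_model()
  runs <- function(kind, seeds) vapply(seeds, function(s)
    run_lfns(gb$model, dummy_data, N = 30, r = 5, delta = 0.02,
             max_iter = 60, sampler = kind, seed = s,
             loglik_fn = gb$loglik)$evidence$logZ_tot, numeric(1))
  z_prior <- runs("prior", 101:115)
  z_gmm <- runs("gmm", 201:215)
  ks <- suppressWarnings(ks.test(z_prior, z_gmm))
  expect_gt(ks$p.value, 0.01)
})
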