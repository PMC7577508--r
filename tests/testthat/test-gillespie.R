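test_that("mass-action propensities follow the multiset convention", {
  net <- bd_model$network
  expect_equal(propensities(net, 5, 1), c(1, 0.5))   # birth k, degradation 0.1*5
  expect_equal(propensities(net, 0, 1), c(1, 0))     # empty reactant pool
  expect_error(propensities(net, -1, 1), "non-negative")

  # dimerization 2X -> 0 at rate c: a = c * choose(x, 2)
  dim2 <- reaction_network("X", list(c(2L)), list(c(0L)), list("c"),
                           par_names = "c")
  expect_equal(propensities(dim2, 5, 3), 3 * choose(5, 2))
  expect_equal(propensities(dim2, 1, 3), 0)
})

test_that("SSA paths are exact for the birth-death process", {
  net <- bd_model$network
  # transient first moment E[X(t)|X(0)=0] = (k/gamma)(1 - exp(-gamma t))
  set.seed(42)
  tpts <- c(1, 10, 50)
  nrep <- 10000
  draws <- matrix(NA_real_, nrep, length(tpts))
  for (i in seq_len(nrep))
    draws[i, ] <- simulate_ssa(net, 1, t_grid = tpts)$grid_states[, 1]
  expected <- 10 * (1 - exp(-0.1 * tpts))
  for (j in seq_along(tpts)) {
    se <- sd(draws[, j]) / sqrt(nrep)
    expect_lt(abs(mean(draws[, j]) - expected[j]), 3 * se)
  }
  # the immigration-death process started at 0 is exactly Poisson
  # distributed at every t: chi-squared GOF at t = 50
  x_inf <- draws[, 3]
  lam <- 10 * (1 - exp(-0.1 * 50))
  breaks <- c(-0.5, seq(3.5, 16.5), Inf)
  obs <- table(cut(x_inf, breaks))
  pr <- diff(ppois(c(-1, 3:16, Inf), lam))
  chi <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(chi$p.value, 0.001)

  # zero reactions: state frozen at x0
  empty <- reaction_network("X", list(), list(), list(), x0 = 7L)
  path <- simulate_ssa(empty, numeric(0), t_grid = c(1, 5, 10))
  expect_true(all(path$grid_states == 7L))

  # reproducibility under a fixed seed
  set.seed(9); a <- simulate_ssa(net, 1, t_grid = 1:20, record_jumps = TRUE)
  set.seed(9); b <- simulate_ssa(net, 1, t_grid = 1:20, record_jumps = TRUE)
  expect_identical(a, b)
  # state changes equal the stoichiometry of +/-1
  expect_true(all(abs(diff(a$jump_states[, 1])) == 1))
})

test_that("fixture generation produces the documented observation sets", {
  d <- generate_fixture("birth_death", M = 3, seed = 11)
  expect_equal(d$M, 3)
  expect_equal(d$n_y, 1)
  expect_equal(length(d$times[[1]]), 30)
  # late-time level is near the stationary mean 10
  late <- unlist(lapply(d$y, function(m) m[20:30, 1]))
  expect_lt(abs(mean(late) - 10), 4)

  # zero observation noise reproduces the integer read-out exactly
  d0 <- generate_fixture("birth_death", M = 1, noise_sigma = 0, seed = 2)
  expect_true(all(d0$y[[1]] == round(d0$y[[1]])))

  # identical seed, identical data
  expect_equal(generate_fixture("birth_death", seed = 5),
               generate_fixture("birth_death", seed = 5))
  expect_error(generate_fixture("unknown_model"), "arg")
})

test_that("transcription fixture has the staged-elongation structure", {
  m <- example_model("transcription")
  expect_equal(m$network$n_x, 11)
  expect_equal(m$network$n_R, 12)
  # default lambda = 4 per minute makes the mean stage-traversal time
  # 8 / lambda = 2 minutes
  expect_equal(unname(8 / m$theta_true["lambda"]), 2)
  # dwell time in the observable region is Erlang(8, lambda): simulate one
  # RNA through the chain and check the mean traversal
  chain <- reaction_network(
    paste0("R", 1:9),
    lapply(1:8, function(i) { v <- rep(0L, 9); v[i] <- 1L; v }),
    lapply(1:8, function(i) { v <- rep(0L, 9); v[i + 1] <- 1L; v }),
    as.list(rep(4, 8)), x0 = c(1L, rep(0L, 8)))
  set.seed(21)
  arrivals <- replicate(3000, {
    p <- simulate_ssa(chain, numeric(0), t_grid = 100, record_jumps = TRUE)
    max(p$jump_times)
  })
  expect_lt(abs(mean(arrivals) - 2), 3 * sd(arrivals) / sqrt(3000))

  dtr <- generate_fixture("transcription", M = 2, seed = 3)
  expect_equal(dtr$M, 2)
  expect_equal(dtr$n_y, 1)
})
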