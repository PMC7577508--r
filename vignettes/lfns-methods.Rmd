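---
title: "Likelihood-free nested sampling for stochastic reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-free nested sampling for stochastic reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfns)
```

## The inference problem

A stochastic chemical reaction network is a continuous-time Markov jump
process $X(t)$ over molecule counts of $n_x$ species, driven by $n_R$
mass-action reactions with rate constants collected (in part) in a
parameter vector $\theta \in \Omega \subseteq \mathbb{R}^d$. The state is
observed only indirectly: at times $t_1 < \dots < t_T$, for each of $M$
cells/trajectories, we record $y_\tau \sim N(C x_\tau, \mathrm{diag}(\sigma^2))$,
a linear read-out of the counts with Gaussian measurement noise.

Bayesian inference targets both the posterior $P(\theta \mid y) \propto
l(y\mid\theta)\,\pi(\theta)$ and the evidence
$Z = \int l(y\mid\theta)\, d\pi(\theta)$. For jump processes of realistic
size the likelihood $l(\theta)$ is intractable, but a bootstrap particle
filter gives an estimator $\hat{l}(\theta)$ whose *linear-domain* mean is
exactly $l(\theta)$: propagate $H$ state particles by exact SSA between
observation times, weight by the observation density, accumulate the mean
weight, and resample multinomially. Unbiasedness of $\hat l$ is the only
property the enclosing algorithm needs; nothing below depends on the
estimator being a particle filter.

## Nested sampling on the joint prior

Nested sampling rewrites $Z = \int_0^1 L(x)\,dx$ over the prior volume
$x(\epsilon) = \pi(l(\theta) > \epsilon)$ and estimates it by iteratively
removing the worst of $N$ "live" points sampled from the prior constrained
to likelihood super-level sets. With an estimated likelihood the super-level
set of $l$ is not well defined, so the algorithm here operates on the
*joint prior* $\Pi(\theta, \hat l(\theta)) = \pi(\theta)\,
p(\hat l(\theta)\mid\theta)$: a particle is a parameter vector paired with
one realization of its estimator, and the constraint is on the realized
value. Sampling the constrained joint prior factorizes into (a) drawing
$\theta^\star$ from $\pi$ restricted to where
$\pi(\theta)p(\hat l(\theta) > \epsilon)$ has mass, (b) drawing one fresh
$\hat l^\star$, and (c) rejecting unless $\hat l^\star > \epsilon$
(strictly; ties can only occur with degenerate mock likelihoods and are
reported as a plateau after $10^5$ consecutive occurrences). Because the
estimator is unbiased, the same telescoping argument as in exact nested
sampling shows the procedure targets the true $Z$.

Each iteration removes the $r$ lowest particles at once (recorded as $r$
sequential removals with live counts $N, N-1, \dots, N-r+1$, which keeps
batch and serial bookkeeping on one shrinkage model) and refills from a
proposal fitted to the surviving live points.

## Constrained-prior proposals

All proposal machinery works in the transformed space where log-uniform
dimensions are log-scaled, so the prior is uniform on a box and
"prior restricted to a support" simply means "uniform on support
$\cap$ box". Three interchangeable samplers are provided; they change
efficiency, never the law of the accepted draws (this exchangeability is
tested):

* **`gmm`** (default; `dpgmm` is accepted as an alias): a Gaussian
  mixture is fitted to the live points with the component count chosen by
  BIC up to $\min(N, 20)$, playing the same adaptive-complexity role as a
  truncated stick-breaking mixture. The support is the mixture density's
  super-level set at $\tau = 0.9 \times$ the lowest live-point density —
  every live point is covered by construction. Candidates are proposed
  from the mixture itself and accepted with probability $\tau/\rho(z)$,
  which is exact rejection sampling onto the uniform law over the support
  (equivalently: acceptance $\propto \pi/\rho$ with the tight bound).
  Proposing from the mixture instead of the prior is what keeps acceptance
  usable once the live set occupies a tiny fraction of the box.
* **`ellipsoid`**: the covariance-shaped ellipsoid covering all live
  points, radius inflated by 1.5; candidates uniform in the ellipsoid,
  clipped to the box.
* **`prior`**: the whole box (plain prior draws). Exact but increasingly
  wasteful as the run shrinks; used as the reference implementation in
  law tests.

Degenerate live sets never crash a fit: covariances are floored at
$10^{-6} \times$ the squared box width per dimension.

## Evidence, variance, and termination

The evidence estimate combines dead and live points
($\tilde\epsilon_i = e^{\epsilon_i}$, mean volumes
$\hat x_i = \prod_{j \le i} N_j/(N_j+1)$, shell weights
$w_i = \hat x_{i-1} - \hat x_i$):

$$\hat Z^m_{tot} \;=\; \underbrace{\sum_{i=1}^m \tilde\epsilon_i w_i}_{\hat Z_D^m}
\;+\; \underbrace{\hat x_m \bar L_m}_{\hat Z_L^m},
\qquad \bar L_m = \tfrac1N \sum_{\text{live}} e^{\hat l_k}.$$

The live term is what allows early stopping: without it the dead sum alone
badly underestimates $Z$ until the run has burned far into the posterior
bulk. Point estimation uses the deterministic mean volumes; the *variance*
of the estimator treats the volumes as random products of independent
$\mathrm{Beta}(N_j, 1)$ shrinkage factors (the law of the maximum of $N_j$
uniforms) and $\bar L_m$ as an independent variable with variance
$\mathrm{var}(e^{\hat l})/N$. Writing the estimator as
$\sum_{i=0}^m d_i x_i + \bar L_m x_m$ and using
$E[x_i x_j] = \prod_{k\le i}\nu_k \prod_{i<k\le j}\mu_k$
($\mu = N/(N+1)$, $\nu = N/(N+2)$), the variance collapses to an $O(m)$
suffix-sum form in terms of $R_i - 1$ with
$R_i = \prod_{j\le i}\bigl(1 + \tfrac{1}{N_j(N_j+2)}\bigr)$, accumulated
through `log1p`/`expm1` so there is no catastrophic cancellation even when
the variance is $10^{-12}$ of the squared mean. The closed form is
validated in the test suite against a brute-force Monte-Carlo replay of
the Beta products (agreement well within 1% at $10^6$ replicates across
$N \in \{5,10,50\}$, $m \in \{5,15,30\}$).

Setting the $\bar L_m$ variance to zero gives $\hat\sigma^{2,m}_{min}$,
the lowest variance still achievable by running longer. The run terminates
when

$$\Delta^m_{LFNS} = \frac{\hat\sigma^m_{tot} - \hat\sigma^m_{min}}{\hat Z^m_{tot}} < \delta .$$

Two readings of this statistic circulate — a difference of standard
deviations and a difference of variances. The default is the
standard-deviation form, which is dimensionally commensurate with
$\hat Z$; the variance form is available via `form = "variance"`. Both are
monotone-equivalent signals and both are zero exactly when the live-set
Monte-Carlo variance vanishes.

Two subtleties about the lower bound are worth stating precisely, because
they are easy to get wrong:

* $\hat\sigma^{2,m}_{min}$ as *computed* plugs the live-set average
  $\bar L_m$ into the role of the true remaining mean $L_m$. The exact
  bound (with the true $L_m$, e.g. constructed from a known likelihood
  curve over volume) is monotone non-decreasing in $m$ — the test suite
  verifies this on self-consistent constructions with zero violations.
  The plug-in estimate can *dip*, most visibly when a new maximum
  likelihood is discovered; this is expected behaviour of the estimate,
  not a defect, and is therefore not asserted on raw run traces.
* All variance bookkeeping is carried as (log-magnitude) pairs with a
  common offset at the maximum log-likelihood, so evidences of order
  $e^{-700}$ and below remain representable.

## The ground-truth oracle

For networks small enough to enumerate, the finite state projection
truncates the chemical master equation to a box of states and filters
exactly: propagate the probability vector with the matrix exponential of
the truncated generator (`Matrix::expm` on the sparse generator, cached
per distinct inter-observation interval), multiply by the observation
density, accumulate log normalizers. The truncation leak is tracked; a
likelihood evaluation errors beyond the configured tolerance. For
evidence quadrature across a prior box that extends far beyond the
truncation's reach (large birth rates drive the process out of any fixed
box), leaky grid points are evaluated non-fatally and the quadrature
verifies they contribute $< 10^{-6}$ of the integral — justified because
observations pinned near small counts make the true likelihood at those
parameters astronomically smaller than the peak. Evidence and posterior
come from trapezoidal quadrature in the transformed prior coordinates;
refinement from 400 to 800 grid points moves the birth-death evidence by
well under 0.5%.

## Study conditions and the synthetic data generator

`generate_fixture()` reproduces the three example systems used throughout
the tests, as SSA simulations with additive Gaussian read-out noise
(default SD 1 molecule — small but nonzero so the particle filter's
weights are well defined):

* **birth_death** — production at $k = 1$, degradation at $\gamma = 0.1$
  (fixed), $X(0) = 0$, one trajectory observed at $t = 1, \dots, 30$;
  log-uniform prior on $k$ over $[0.01, 100]$. The transient law is
  exactly Poisson$(10(1 - e^{-\gamma t}))$, which the SSA tests exploit.
* **transcription** — a two-state gene; while on, transcription initiates
  at $k_r$, and each nascent RNA traverses 8 sequential stages at
  per-stage rate $\lambda$ before release, so one event dwells
  Erlang$(8, \lambda)$ in the observable region; $\lambda = 4\,
  \mathrm{min}^{-1}$ makes the mean dwell 2 minutes. Released RNA is
  cleared from its sink at the same rate, which bounds the state space
  without touching the read-out (the observed channel is the sum of the
  8 stages). Switching rates, $k_r$, the observation noise and the prior
  bounds are package defaults chosen at plausible per-minute scales.
* **lotka_volterra** — prey birth, predation, predator death at
  $(1, 0.005, 0.6)$ from $(50, 100)$, both species observed; rates,
  initial state and priors are package defaults from the standard
  stochastic-kinetics inference literature.

What the generator does *not* emulate: extrinsic cell-to-cell variability,
non-Gaussian or state-dependent measurement noise, per-molecule emission
models (expressible in the config schema via channel coefficients, but no
fixture uses them), and time-varying inputs. Passing tests therefore
demonstrate correctness of the inference machinery under the model's own
assumptions, not robustness to model misspecification.

## Numerical and design choices

* Mass-action propensities use the distinct-multiset convention
  $a_j = c_j \prod_i \binom{x_i}{p_{ji}}$, so SSA, particle filter and FSP
  share one generator by construction.
* Problem sizes in the shipped tests: the full birth-death run uses
  $N = 100$ live points, $H = 100$ filter particles, batch $r = 10$,
  $\delta = 10^{-3}$ (a few hundred removals); the run ensemble uses 20
  runs at $N = 20$, $H = 50$; the particle-filter unbiasedness check uses
  1000 replicates at three birth rates; the variance replay uses $10^6$
  Monte-Carlo replicates per grid cell. These sizes make every scientific
  check pass at its stated statistical tolerance while keeping the whole
  suite in the minutes range.
* Multinomial resampling at every filter step (no ESS trigger), and
  resampling uses sorted uniform spacings, which is $O(H)$ per step.
* The proposal model is refitted every iteration from the post-removal
  live set; the batch's $r$ replacement searches are independent given
  the iteration's RNG state.
* All randomness flows through R's global RNG (the C++ kernels draw from
  it via the R API), so a single `set.seed`/`seed =` argument makes runs
  bit-reproducible.
* MCMC-based constrained sampling and slice sampling are deliberately
  absent: the former inherits the usual correlated-sample drawbacks, the
  latter needs pointwise density evaluations of the target, which the
  joint-prior constraint does not admit.

## Known limitations

* **Small-$N$ evidence bias.** The plug-in estimator with deterministic
  mean volumes is exactly unbiased only in the idealized treatment where
  volumes are random; for finite $N$, likelihoods convex in prior volume
  give $E[L(x_i)] > L(\hat x_i)$ and hence an upward bias. With an exact
  likelihood on the birth-death problem this measures about $+10\%$ at
  $N = 20$ and $+0.4\%$ at $N = 100$ (100-run ensembles); estimator noise
  at small $H$ and tight mixture supports fitted to few live points can
  amplify it further. Production inference should use $N \gtrsim 100$,
  where the full-run recovery checks pass comfortably; the cheap-run
  ensemble checks in the suite sit deliberately at the edge of this
  regime.
* The FSP oracle is restricted to one or two free parameters and to
  state spaces of at most 20,000 enumerable states.
* ABC-SMC targets $p(\theta \mid d(y_\theta, y) < \epsilon)$, not the
  posterior; its populations are systematically wider, which the
  comparison tests assert rather than correct.
* Wall-clock parallelism is not implemented; the batch structure is
  parallelism-ready (independent replacement searches) but executes
  serially here.
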