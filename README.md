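# lfns — likelihood-free nested sampling for stochastic reaction networks

Mechanistic models of gene expression and signalling are usually stochastic
chemical reaction networks: continuous-time Markov jump processes over
molecule counts, observed noisily at a few timepoints in a few cells. For
such models the likelihood $l(y\mid\theta)$ is intractable, which rules out
vanilla MCMC and classical nested sampling. This package implements
**likelihood-free nested sampling (LF-NS)** for exactly this setting, for
modellers who want full posteriors *and* the Bayesian evidence
$Z=\int l(y\mid\theta)\,d\pi(\theta)$ with an error bar from a single run.

The core ideas:

* replace the likelihood with a **bootstrap particle filter** estimate
  $\hat l(\theta)$ (exact SSA propagation of $H$ particles; unbiased in the
  linear domain), and run nested sampling on the **joint prior**
  $\Pi(\theta,\hat l(\theta)) = \pi(\theta)\,p(\hat l(\theta)\mid\theta)$,
  which preserves the evidence exactly for any unbiased estimator;
* estimate evidence from dead **and** live points,
  $\hat Z^m_{tot} = \sum_{i\le m} \tilde\epsilon_i w_i + \hat x_m \bar L_m$,
  with mean Beta-shrinkage volumes $\hat x_i = \prod_{j\le i} N_j/(N_j+1)$;
* compute a **closed-form estimator variance** $\hat\sigma^{2,m}_{tot}$
  under the Beta-shrinkage model, plus the lower bound
  $\hat\sigma^{2,m}_{min}$ (the same variance with the live-set Monte-Carlo
  term zeroed), and stop when
  $\Delta^m_{LFNS} = (\hat\sigma^m_{tot}-\hat\sigma^m_{min})/\hat Z^m_{tot} < \delta$;
* draw replacement particles from the prior restricted to the live set's
  region via Gaussian-mixture or ellipsoid density estimates (rejection
  sampling in the log-transformed prior box).

Also included: an exact finite-state-projection (FSP) likelihood/evidence
oracle for small networks, synthetic data generators for three example
systems (birth-death, an 8-stage transcription model, Lotka-Volterra), and
reference implementations of the two standard likelihood-free baselines,
pseudo-marginal particle MCMC and ABC-SMC.

## Worked example

Infer the birth rate of a birth-death process (production at rate $k$,
degradation at $\gamma = 0.1$ fixed; log-uniform prior on $k$ over
$[0.01, 100]$) from one simulated trajectory observed at 30 timepoints:

```r
library(lfns)

model <- example_model("birth_death")          # network + observation + prior
data  <- generate_fixture("birth_death", seed = 1)

run <- run_lfns(model, data, N = 100, H = 100, r = 10,
                sampler = "gmm", delta = 0.001, seed = 203)
run
#> LF-NS run: 470 removals, log Z_tot = -62.9609, converged = TRUE

tail(run$trace[, c("iteration", "eps", "logZ_tot", "delta_lfns", "acceptance")], 1)
#>    iteration       eps  logZ_tot   delta_lfns acceptance
#> 47        47 -59.57764 -62.96089 0.0009950496  0.1449275
```

The run removed 470 particles over 47 iterations and stopped when the
termination statistic dropped below $10^{-3}$: continuing would shrink the
achievable standard deviation by less than 0.1% of $\hat Z$. Against the
exact FSP oracle on the same data:

```r
cfg  <- fsp_config(60)                          # truncate X at 0..60
grid <- exp(seq(log(0.01), log(100), length.out = 400))
ev   <- grid_evidence(model$network, model$obs, model$prior, data, grid, cfg)
ev$logZ
#> [1] -62.84682

abs(run$evidence$Z_tot - ev$Z) / sqrt(estimator_variance(run$evidence)$var)
#> [1] 0.673879    # discrepancy in units of the run's own reported sd
```

The weighted posterior (dead + live particles) overlays the FSP grid
posterior with a 1-Wasserstein distance of about 0.004 in $\log_{10} k$
units. The same pieces are scriptable from a shell through
`inst/scripts/lfns.R` (`simulate`, `pf`, `oracle`, `run`, `pmcmc`,
`abcsmc`, `postprocess` subcommands), each writing a `manifest.json`,
`posterior.csv` and `trace.csv`.

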