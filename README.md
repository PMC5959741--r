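# mcrelease

Monte Carlo simulation and inference of drug release kinetics from
cylindrical solid dosage forms.

## The problem

When a solid tablet (for example a hydroxypropyl methylcellulose, HPMC,
matrix) releases its drug load, the shape of the release curve N(t) — the
amount of drug remaining in the matrix over time — carries the signature of
the physical transport mechanism. Fickian diffusion yields a stretched
exponential (Weibull) profile; stochastic erosion of the polymer matrix
yields near-linear release; swellable matrices often show a mixture that no
single classical model (Weibull, linear, Higuchi) fits over the whole
observation window.

`mcrelease` simulates release with a lattice Monte Carlo heuristic in which
the mechanism is encoded entirely in the **Monte Carlo Micro-Step (MCS)**,
the time increment added to the clock per simulation event:

* diffusion: `MCS = 1 / N(t)`
* erosion: `MCS = |ln u| / lambda`, `u ~ U(0,1)` (exponential waiting times
  with rate `lambda`, the reciprocal polymer half-life)
* hybrid: `MCS = A(k) * N(t)^-nu / lambda1 + B(k) * |ln u| / lambda2`, with
  step-indexed coefficients `A(k), B(k)` chosen among `{1, 1/k, k}`

The drug is a cloud of points inside a cylinder of radius `R` and height
`H`; sites with `(R-1)^2 <= x^2 + y^2 <= R^2` form the unit-thickness *leak
shell* through which molecules are released (radial release only; the axial
faces are sealed). Two kernels are provided: the *shell-removal* kernel
(each step removes every molecule in the leak shell and shrinks `R` by one)
and an explicit single-occupancy *random-walk* kernel with the leak shell as
absorbing boundary.

Given an **observed** release curve, a seeded genetic algorithm inverts the
simulator: it searches the hybrid-MCS parameter space for the candidate
whose ensemble-mean simulated curve minimizes the sum of squared deviations
from the observation. The balance between the recovered deterministic and
stochastic terms (see `mcs_time_shares()`) identifies the dominant release
mechanism.

## Worked example

Simulate a diffusion-governed release from a cylinder with 1745 molecules
(`R0 = 31`, `H = 62`, volume-uniform loading), fit the Weibull model
`N(t) = a exp(-b t^c)`, and summarize 20 replicates:

```r
library(mcrelease)
cfg <- simulation_config(n0 = 1745, R0 = 31, H = 62,
                         sampler_mode = "volume_uniform",
                         mcs = mcs_model("diffusion"), seed = 1)
curve <- simulate_release(cfg)
print(curve)
#> release_curve: 31 points, t in [0, 0.831268], N from 1745 to 2 (n0 = 1745)

fit_weibull(curve)
#> weibull fit (31 points)
#> Parameter      Estimate   Std. Error    t value     Pr(>|t|)
#> a                1844.3       28.428     64.875    4.545e-32
#> b                 35.05       3.7852      9.260    5.112e-10
#> c               0.80458     0.026854     29.961    8.138e-23
#> Residual standard error: 35.5543 on 28 degrees of freedom
#> Log-likelihood: -153.1124

run_ensemble(cfg, n_runs = 20, model = "weibull", seed = 20260909)
#> ensemble_summary: weibull fits over 20 runs (20 converged)
#>               a        b       c
#> mean 1845.63130 33.60634 0.79497
#> sd      6.01635  2.07604 0.01529
#> 25%  1844.53111 32.45924 0.78968
#> 50%  1845.87424 33.35028 0.79352
#> 75%  1847.91208 34.77228 0.80427
```

The fitted shape exponent `c ~ 0.79 < 1` is the Fickian-diffusion signature
(sub-exponential, front-loaded release); its tight spread across replicates
(sd ~ 0.015) shows the Weibull law describes every run of this mechanism.
An erosion simulation (`mcs_model("erosion", lambda = 0.1)`) instead
produces near-linear curves: `fit_linear()` reports R-squared above 0.95
with a negative slope. Mechanism inference from an observed curve:

```r
res <- infer_mcs(observed_curve, ga_config(seed = 1), cfg)
mcs_time_shares(res$best_params, cfg)   # deterministic vs stochastic share
```

## Command line

```sh
inst/cli/mcrelease simulate --config sim.yaml --seed 7 --out curve.csv
inst/cli/mcrelease fit --model weibull --curve curve.csv --out report.json
inst/cli/mcrelease infer --curve obs.csv --ga-config ga.yaml --sim-config sim.yaml --out result.json
```

Every run writes a JSON manifest (`<out>.manifest.json`) with the options,
seed and package version needed to reproduce it.

## Documentation

See the methods vignette (`vignettes/release-mechanisms.Rmd`) for the model,
its assumptions, the tunable parameters, numerical choices, and what the
synthetic-data generator does and does not emulate.
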