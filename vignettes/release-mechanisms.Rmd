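---
title: "Monte Carlo heuristics for drug release mechanisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo heuristics for drug release mechanisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcrelease)
```

## The model

A cylindrical solid dosage form of radius $R$ and height $H$ (lattice
units; one unit is the side of the cuboid a molecule occupies) holds $N(0)
= n_0$ drug molecules. Release is radial only: the axial faces are sealed,
so $H$ is constant. The cross-section is partitioned into an *interior*
($x^2 + y^2 < (R-1)^2$), a unit-thickness *leak shell*
($(R-1)^2 \le x^2+y^2 \le R^2$) through which molecules leave, and a
*restricted* exterior ($x^2+y^2 > R^2$). A molecule that reaches the leak
shell is immediately counted as released and removed.

Time is advanced by the **Monte Carlo Micro-Step (MCS)**, whose functional
form *is* the physical model:

$$\mathrm{MCS}_d = \frac{1}{N(t)}, \qquad
  \mathrm{MCS}_e = \frac{|\ln u|}{\lambda}, \qquad
  \mathrm{MCS} = A(k)\,\frac{N(t)^{-\nu}}{\lambda_1}
               + B(k)\,\frac{|\ln u|}{\lambda_2},$$

with $u \sim U(0,1)$. The diffusion step grows as the matrix empties
(front-loaded, Fickian release); the erosion step is an exponential waiting
time with rate $\lambda$ (the reciprocal polymer half-life, units 1/time),
modelling random chain-scission events; the hybrid template mixes a
deterministic $N$-dependent term with a stochastic noise term through the
step-indexed coefficients $A(k), B(k) \in \{1, 1/k, k\}$. The combination
$A(k)=1/k$, $B(k)=k$ describes a matrix whose early release is
diffusion-dominated and whose late release is governed by stochastic
polymer--fluid interactions, as observed for swellable HPMC tablets.

### Kernels

Two simulation kernels produce a trajectory $(t_k, N_k)$:

* **shell** (default): each step removes *every* molecule currently in the
  leak shell, shrinks $R$ by one, and advances the clock by one micro-step
  evaluated at the post-removal count. It terminates when $R \le 1$ or
  $N = 0$, hence within $\lceil R_0 \rceil$ steps. With
  `per_molecule = TRUE` the clock instead accrues one micro-step per removed
  molecule, evaluated as the count decrements — under $\mathrm{MCS}_d$ this
  collapses the trajectory onto $N = n_0 e^{-t}$ exactly, which is why the
  one-step-per-shell accounting is the default.
* **walk**: molecules are quantized to integer lattice sites (collisions
  resolved to the nearest free site) and perform a single-occupancy random
  walk over the 6-neighbour (von Neumann) stencil; moves into occupied or
  restricted sites are rejected, moves into the leak shell are absorptions.
  One micro-step per attempted move. The circumscribing radius is held at
  $R_0$ here: recomputing $R$ from the farthest surviving molecule would put
  the outermost molecules inside a moving leak band and conflate the two
  kernels' shrinkage mechanisms, so shrinkage is the shell kernel's
  heuristic only.

### Point generation

Two radial samplers are exposed. The classical generator (`"paper"`,
default) draws angle, radius and height each uniformly — a radially
*biased* density ($\propto 1/r$), faithful to the generator historically
used with this heuristic. `"volume_uniform"` uses $r = (R-1)\sqrt{u}$ and is
uniform per unit volume. The choice matters: under the shell kernel with
$\mathrm{MCS}_d$, the acceptance suite measures a mean Weibull shape of
$c \approx 0.79$ for volume-uniform loading versus $c \approx 1.0$ for the
biased sampler (a radially uniform count per annulus gives a nearly
constant per-shell removal). Reference single-run diffusion fits for this
method report $c \approx 0.756$ — reproduced by the volume-uniform reading —
while reference erosion ensembles show linear fits with $R^2 > 0.95$,
which the *biased* sampler yields on the default geometry (median
$R^2 \approx 0.98$ vs $\approx 0.92$ volume-uniform). Neither sampler
reproduces both reference ensembles, so both are first-class options: the
acceptance tests use volume-uniform for the diffusion/Weibull band and the
default sampler for erosion linearity, and the discrepancy is documented
here rather than hidden.

A minimum inter-molecule distance $d$ is enforced by greedy random
thinning (pick a random survivor, delete everything strictly closer than
$d$, repeat), re-drawing progressively larger candidate pools until exactly
$n$ survivors exist; pool growth is bounded (at most $20n$ candidates) so an
infeasible packing fails with a diagnostic instead of exhausting memory.

## Fitting

Three classical dissolution models are fitted with full diagnostics
(estimate, SE, $t$ value, two-sided $p$ on residual dof — no multiplicity
correction, matching standard single-fit reporting):

* **Weibull** $N(t) = a e^{-b t^c}$, bounded nonlinear least squares
  (`nls`, `"port"`). Initialization: $a_0 = N(0)$, a restart grid
  $c_0 \in \{0.3, 0.5, 0.7, 1.0\}$, $b_0$ from log-linearization at the
  curve midpoint; lowest-RSS converged restart wins. Bounds
  $0 < a \le 10N(0)$, $b > 0$, $c > 0$ in the default grid. The $t = 0$
  point is *kept* (it anchors $a$ near $n_0$). A negative-$c$
  parameterization — which arises when fitting fractional-release data,
  where the curve rises — is a fallback restart only; it drops exact-zero
  times with a warning because $t^c$ is singular at 0 for $c < 0$.
  Non-convergence returns `converged = FALSE`, never an error.
* **linear** $N(t) = a + bt$ (OLS; reports $R^2$, $F$-test $p$,
  log-likelihood), the reference model for erosion.
* **Higuchi** released$(t) = k_H\sqrt{t}$, through the origin, on released
  amount or fraction.

Erosion-mode reference fits are made on $N(t)$ (not fraction); the linear
model is written in $N(t)$ and the two differ only by an affine map.

`run_ensemble()` repeats simulate-and-fit over deterministically derived
per-run sub-seeds and aggregates parameter and $p$-value distributions;
non-converged fits are counted and excluded.

## Inference

`infer_mcs()` inverts the simulator: a generational GA (tournament size 3,
BLX-$\alpha$ blend crossover with $\alpha \in [-0.25, 1.25]$, bounded
Gaussian mutation with sd $= 0.1 \times$ gene range, elitism of 1) searches
the genome
$(\nu,\ \log_{10}\lambda_1,\ \log_{10}\lambda_2,\ A\text{-form},\
B\text{-form},\ \log_{10}\text{tscale})$,
minimizing $\sum_i (\hat N(t_i) - \bar N(t_i))^2$ where $\bar N$ is the
mean of `ensemble_size_per_candidate` simulated trajectories linearly
interpolated at the observed times. Design choices, all made where the
procedure itself is underdetermined:

* **Common random numbers**: one fixed set of simulation sub-seeds is used
  for every candidate evaluation, making the objective deterministic,
  candidate comparisons fair, and the elitist best-objective trace
  non-increasing by construction.
* **Defaults** (population 40, 60 generations, crossover 0.8, mutation 0.2)
  are conventional GA settings; 10 simulations per candidate keeps
  desk-scale runtime, with 50 available by configuration for
  reference-grade averaging.
* **Identifiability**: a constant coefficient multiplying a rate is not
  separately estimable ($A$ and $\lambda_1$ enter only as $A/\lambda_1$),
  so constant forms are fixed at 1 and magnitude lives in the log-searched
  rates. The form selectors are continuous genes rounded to
  $\{1 \to \text{constant}, 2 \to 1/k, 3 \to k\}$; collapsing a gene's
  bounds pins it.
* **Time units**: observed curves rarely share the simulator's arbitrary
  units, so a global scale factor is one extra gene (`log10_tscale`),
  pinned to 1 by default since synthetic observations are native-unit.
* Candidates whose simulations cannot span the observed time range get an
  infinite objective (direct `objective_ssq()` calls raise an
  extrapolation error instead); the objective compares fractional release
  by default, remaining amounts on request.

`mcs_time_shares()` reports the deterministic/stochastic split of total
simulated time under recovered parameters — the mechanism verdict: on
synthetic data the acceptance suite recovers $\nu$ within $\pm 0.25$ from a
hybrid-generated curve and assigns a stochastic share below 10% to
diffusion-generated data.

## The synthetic world, and what a green test establishes

The default geometry ($n_0 = 1745$, $R_0 = 31$, $H = 2R_0 = 62$, $d = 0$)
reconstructs the reference single-run diffusion experiment from its own
fit report: 28 residual degrees of freedom with 3 parameters imply 31 curve
points, i.e. one initial record plus 30 shell steps ($R_0 = 31$), and the
amplitude estimate $a \approx 1744.9$ pins $n_0 \approx N(0) = 1745$.
Erosion ensembles use $\lambda = 0.1$ and 50 replicates; inference tests
use a reduced cylinder ($n_0 = 200$, $R_0 = 11$) for runtime, with the
hybrid truth $(\nu, \lambda_1, \lambda_2) = (1, 0.005, 10)$ chosen so both
MCS terms contribute comparably (each is identifiable but neither
dominates).

The generator emulates ideal, monodisperse, non-interacting molecules in a
rigid cylinder: no swelling, no axial release, no concentration-dependent
diffusivity, no dissolution-medium chemistry. Synthetic observed curves are
ensemble means of the simulator itself plus optional Gaussian noise.
A green suite therefore establishes internal consistency (kernels,
estimators and the GA recover what the simulator generated) and agreement
with reference ensemble statistics under the stated geometry — not
predictive accuracy for real HPMC tablets, whose curves involve swelling
physics this lattice deliberately omits.

## Numerical choices

* Uniform draws of exactly 0 or 1 (infinite / zero erosion steps) are
  resampled, keeping the clock finite and strictly increasing.
* If the shell kernel empties the matrix, the final step is clocked at
  $N = 1$ (the $1/N$ step is otherwise undefined at $N = 0$).
* All randomness flows through per-call seeds; sub-seeds are derived by a
  seeded 31-bit integer draw, and the caller's RNG state is always
  restored. Identical seed, identical output, bit for bit.
* Leak-shell membership uses the *current* radius uniformly in $z$; closed
  interval on both shell edges, so the three site classes partition the
  plane.
* CSV interchange is comma-separated with '.' decimals and mandatory
  headers; YAML configs reject unknown keys (a typo in a stochastic
  experiment is otherwise silent).

## Known limitations

* The walk kernel is a reference implementation (R-level loop, full state
  audit-friendly); use the shell kernel for large $n_0$ or long runs.
* $\lambda_1, \lambda_2$ are free parameters; no mapping from polymer
  viscosity grades to rates is provided.
* The GA explores $\{$constant, $1/k$, $k\}$ coefficient forms only; other
  time dependences of $A, B$ require extending the genome.
* Weibull parameters are strongly correlated on shell-kernel curves
  (roughly 30 points); single-run estimates of $a, b$ scatter far more than
  $c$, and only the shape exponent should be interpreted mechanistically.
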