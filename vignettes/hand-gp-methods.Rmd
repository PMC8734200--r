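---
title: "Hand-GP: non-parametric synergy scoring for two-drug checkerboards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hand-GP: non-parametric synergy scoring for two-drug checkerboards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handgp)
```

## The problem

Two compounds applied together can inhibit a biological readout more
(synergy) or less (antagonism) than expected from their individual
potencies. Deciding which requires a *null reference*: the response surface
the combination would show if the drugs did not interact. `handgp` scores
checkerboard experiments (an `n1 x n2` dose matrix with monotherapy rows and
columns) in three steps:

1. **Fit the full response surface non-parametrically** with a Gaussian
   process (GP) whose kernel operates on warped doses
   `u = log(1 + x / l)`, capturing the log-dose dependence of cellular
   responses while remaining defined at dose 0;
2. **Construct the null reference** from the *fitted* monotherapy curves by
   the Hand construction -- the infinitesimal form of Loewe additivity and
   the only classical null model that satisfies sham combination,
   commutativity and associativity;
3. **Score synergy** as `null - fit` (for inhibitory data): a per-dose
   effect surface with credible bands, and a single volume-difference
   summary.

Hill-curve and MuSyC baselines are included so the non-parametric fit can be
compared against the standard parametric treatments of the same data.

## The GP surface model

Responses are modelled as `y = f(x1, x2) + e`, `e ~ N(0, sigma^2)`, with a
zero-mean GP prior on `f` under the product logarithmic kernel

    k(x, x') = sigma_f^2 exp( -1/2 * sum_i ( log(1 + x_i/l_i) - log(1 + x_i'/l_i) )^2 ).

For doses much smaller than `l_i` this reduces to the squared-exponential
kernel; for doses much larger it acts on log-dose. The four hyperparameters
are the amplitude `sigma_f`, the per-axis length scales `l1`, `l2` (their
ratio is the potency ratio of the two drugs) and the noise level `sigma`.
Posterior means and variances come from the exact conjugate formulas via
Cholesky factorisation; designs here are at most a few hundred wells, so no
approximations are needed. A relative jitter of `1e-8 * sigma_f^2` is added
to Gram diagonals so replicate wells (duplicated dose pairs) remain
factorisable.

Because the prior mean is zero, predictions far outside the design revert
toward 0; monotherapy slices are therefore only extrapolated moderately
beyond the design span (see the Hand construction below) and flagged where
they had to be clamped.

### Priors and inference

Weakly informative Gamma priors are moment-matched to the design:

* length scale `l_i`: mean `c * Dmax_i`, variance `0.1 * (c * Dmax_i / 2)`.
  The constant `c` measures how strongly the effect changes over the
  observed dose range. Its automatic value is the ratio of the minimal to
  the maximal monotherapy response: for a curve that falls two orders of
  magnitude this gives `c ~ 0.01` and length scales deep in the log-dose
  regime, while a flat curve gives `c ~ 1` and a length scale at the dose
  span (an essentially linear, very smooth kernel). The orientation of this
  ratio matters: taking it `>= 1` would place the length scale far above the
  dose span, linearising the warp and forcing a near-constant surface.
* amplitude `sigma_f`: mean `Emax_obs / 2`, variance `0.1 * (Emax_obs / 2)`,
  with `Emax_obs` the maximum response level observed. The prior targets the
  *standard deviation*: a zero-mean GP can only reach responses on the scale
  of the data if `sigma_f` is on that scale (placing the same numbers on the
  variance `sigma_f^2` pins the amplitude near `sqrt(50)` for percent data
  and the fit degenerates to a flat surface plus noise).
* noise `sigma`: Gamma(2, 1) on the percent scale, Gamma(0.14, 1.14) on the
  fraction scale -- the same prior up to the response scale.

Hyperparameters are sampled with Hamiltonian Monte Carlo in
`phi = log(l1, l2, sigma_f, sigma)` with the Jacobian correction: 5 leapfrog
steps, target acceptance 75%, and the step size chosen as the largest
candidate from a log-spaced grid whose short pilot run reaches the target
acceptance. Reference settings are 1000 burn-in and 100,000 kept samples;
every stochastic operation takes an explicit integer seed and is
reproducible bit for bit. Chains are summarised by 95% highest-posterior-
density (HPD) intervals and split-Rhat. Surfaces are computed by plugging in
the posterior-mean hyperparameters (variances averaged on the variance
scale); a deterministic MAP mode (`mode = "map"`, multi-start L-BFGS-B on
the same log posterior) gives near-identical surfaces in a fraction of the
time and is the default for interactive use.

## The Hand null reference

The Hand model splits the doses `x1`, `x2` into `N` small partitions and
applies them alternately along the two monotherapy curves: each step
converts the current effect into an equivalent dose of the acting drug
(numerical inversion of the fitted curve by monotone linear interpolation on
the dense prediction grid), advances that dose by one partition, and reads
the new effect off the curve. Per-node partition counts follow the grid:
`N_i` is the index of the grid point nearest to `x_i` (ties toward the lower
index), so finer grids automatically refine the construction.

Two numerical choices matter:

* **Order averaging.** A fixed application order (drug 1 first) leaves an
  `O(1/N)` asymmetry under swapping the drugs -- measurably ~6e-4 of the
  effect range at N = 200 -- although commutativity is a defining property
  of the ideal Hand model. Each round here averages the two application
  orders; the round map is then symmetric in the drugs, swap-invariance
  holds to machine precision, and the splitting error drops to second
  order. Sham combinations and linear curves are unaffected.
* **Invertibility.** GP monotherapy means can be non-monotone on noisy
  data. The construction inverts the longest strictly monotone segment
  starting at dose 0, clamps effects outside its range, and flags every
  affected node instead of failing the surface. Monotherapy slices are
  evaluated on an extended axis (log1p spacing continued to 4x the maximal
  design dose) because the running equivalent dose at high combination doses
  legitimately exceeds the design span.

Under these choices the construction reproduces `f(x1 + x2)` for sham
combinations (within 0.5% of the effect range at N = 100), is exactly
additive for linear curves at any `N`, and agrees with the implicit Loewe
isobole solution within 1% of the effect range on additive Hill surfaces --
all verified in the test suite.

## Synergy scores

The effect surface is `null - fit` for inhibitory data (positive = more
inhibition than expected = synergy), with a 95% band from the fitted
surface's predictive variance; the null, built from the same posterior's
monotherapy slices, is treated as fixed, which avoids double-counting the
shared uncertainty and matches the near-invisible intervals typical of
effect-curve plots. A per-design-dose call is `"additive"` exactly when 0
lies inside the band.

The summary score is the difference of the volumes under the null and
fitted surfaces, computed by triangulating the prediction grid (each
rectangular cell split along a diagonal -- a Delaunay triangulation of the
node set; the two diagonal choices agree to discretisation error and
exactly on planes). **Integration coordinates:** log1p-spaced grids are
integrated over their warped coordinates `u = log(1 + x / l)` rescaled to
`[0, 100]` per axis. This makes the score dimensionless and independent of
dose units (a volume `V` corresponds to a mean effect of `V / 1e4` response
units), weights the pharmacologically active log-dose decades evenly, and
is invariant to grid density. Integrating in linear dose units instead
lets the highest dose decade -- where inhibitory responses are all near
zero -- dominate the integral, and in simulation the score then misses the
direction of mild interactions. Linear grids (used for the analytic volume
identities) integrate in plain dose units. The volume band integrates the
pointwise 1.96-sd half-width over the same coordinates, treating errors as
fully correlated; this is conservative, and the overall call is additive
when the band covers 0.

The MuSyC baseline mirrors the construction: a 12-parameter
(`E0..E3, h1, h2, C1, C2, alpha12, alpha21, gamma12, gamma21`) steady-state
surface fit by bounded least squares, an additive-constrained refit
(`alpha = gamma = 1`, `beta = 0`), and the same volume difference on the
same grid. Parametric-bootstrap confidence intervals are available for both Hill and
MuSyC fits: responses are resampled as `fit + N(0, s_b^2)` and refit, with
percentile intervals over B replicates. Each replicate's noise level `s_b`
is drawn from the scaled inverse-chi-square distribution of the
df-corrected residual variance -- with only a few residual degrees of
freedom the variance estimate itself is uncertain, and resampling at the
point estimate collapses all intervals whenever a fit happens to be tight
(measured coverage dropped to ~85%; with the variance draw it is 93-98%,
computed in the acceptance suite).

## The synthetic-data generator

`simulate_combination()` emulates the classic simulated benchmark
conditions: two shared-asymptote Hill monotherapies combined through the
interaction isobole

    d1/D1(E) + d2/D2(E) + alpha * d1 d2 / (D1(E) D2(E)) = 1,

solved for `E` by bracketed bisection (tolerance 1e-10 of the effect span;
for `alpha < 0` the physical root is the first upward crossing from the
deep-effect end, since the interaction term diverges near zero effect).
`alpha = 0` is exact Loewe additivity; positive values give synergy,
negative antagonism. Defaults are the benchmark 6x6 design
(drug A doses 0, 2, 5, 10, 20, 50; drug B doses 0, 0.2, 0.5, 1, 2, 5),
percent scale, `alpha = 0.5` (mild synergy), monotherapy parameters
`(E0 = 100, Emax = 0, h = 0.87, C = 8.16)` and `(h = 1.27, C = 0.79)`
matching published Hill fits to that design, and i.i.d. Gaussian noise with
sd 2 -- the level implied by the percent-scale noise prior. `gp_sample()`
draws surfaces directly from the GP prior for hyperparameter-recovery
studies.

What the generator does *not* emulate: plate/batch effects, replicate
correlation structure, heteroscedastic counting noise, non-monotone
off-target responses. Passing the calibration suites therefore shows the
pipeline is correct and well calibrated *under the stated model family*,
not that every real screen will behave as well.

## Study sizes used by the test and acceptance suites

All simulation studies are seeded and sized to run comfortably on one CPU;
the sizes are package choices, stated here once:

* null calibration: 50 replicates of the 6x6 mild-noise design at
  `alpha = 0`, reduced HMC (500 burn-in, 5000 samples); direction recovery:
  20 replicates each at `alpha = +2` and `alpha = -0.5`;
* hyperparameter recovery: 40 replicates of an 11x11 GP-sampled design,
  HMC with 300 burn-in and 2000 samples, component-wise 95% HPD coverage
  checked against 85%;
* bootstrap calibration: 60 replicate experiments at B = 500;
* the acceptance script analyses one Greco-type 6x6 study and one 11x11
  noise-free strong-synergy study end to end with HMC at 500 burn-in /
  5000 samples.

## Known limitations

* The zero-mean GP reverts to 0 far outside the design; combination
  regions far beyond the measured dose range should not be interpreted.
* The volume band treats pointwise errors as fully correlated and is
  conservative: mild interactions on small designs are often called
  additive, which is the intended behaviour but costs power.
* The Hand construction requires an invertible monotherapy start; strongly
  non-monotone fitted monotherapies (heavy noise, off-target activation)
  are clamped and flagged rather than modelled.
* Designs below 6x6 give noisy volume estimates and are flagged in screen
  mode; MuSyC additionally approaches one parameter per observation there.
* MuSyC transition rates are fixed at `r1 = r2 = 1` (as in the reference
  implementation); only the 12 listed parameters are fitted.
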