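---
title: "Coupled two-compartment PK models: methods and design notes"
author: "coupledpk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled two-compartment PK models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coupledpk)
```

## The model

`coupledpk` implements a linearly coupled two-compartment oral
pharmacokinetic model for a pair of co-administered drugs X and Y.
Each drug follows the classical oral two-compartment structure — gut
(absorption) compartment, central (plasma) compartment, peripheral
(tissue) compartment, plus first-order elimination from the central
compartment — but every rate constant of one drug is modified linearly
by the partner drug's current amount in a *driving* compartment:

$$
\begin{aligned}
\dot x_0 &= -(a_{abs} + g_{abs}\, y_0)\, x_0\\
\dot x_1 &= (a_{abs} + g_{abs}\, y_0)\, x_0
           - (a_{cp} + g_{cp}\, y_1)\, x_1
           + (a_{pc} + g_{pc}\, y_2)\, x_2
           - (a_{el} + g_{el}\, y_1)\, x_1\\
\dot x_2 &= (a_{cp} + g_{cp}\, y_1)\, x_1 - (a_{pc} + g_{pc}\, y_2)\, x_2
\end{aligned}
$$

and symmetrically for Y with the roles of $x$ and $y$ exchanged.  Here
$x_0, x_1, x_2$ are gut, central and peripheral amounts; the absorption
coupling is driven by the partner's *gut* amount, the central-to-
peripheral and elimination couplings by the partner's *central* amount,
and the peripheral-to-central coupling by the partner's *peripheral*
amount.  A negative coupling coefficient is antagonistic (it slows the
partner process); a positive one is promoting.  With all eight
coefficients zero the two drugs decouple into independent classical
models, whose central amount has the tri-exponential closed form
implemented in `analytic_uncoupled()` — the package's analytic oracle.

Two bookkeeping extensions are part of the implementation rather than
the model: (i) each drug carries a cumulative-elimination state, defined
as the integral of its elimination flux, so that
gut + central + peripheral + eliminated equals the dose at every time
(the mass-balance invariant the tests enforce at 1e-8 relative); and
(ii) plasma concentration relates to central amount through the
apparent central volume, `amount = Vc * concentration`.

Units: the canonical internal scale is 10^3 mg for amounts and hours
for time.  Rates are h^-1 and interaction coefficients 10^3/(mg h).
All file input is converted to this scale once at ingest.

## Simulation and PK metrics

`pk_simulate()` integrates the system with `deSolve::lsoda`
(stiff-capable, adaptive) at relative tolerance 1e-9 and absolute
1e-12, storing a dense output grid (default 0.001 h).  The
right-hand side is compiled C for speed; an identical pure-R
implementation (`coupled_rhs()`) is kept and cross-checked in the test
suite so the two routes validate each other.

PK metrics interpolate the dense grid with a cubic spline: Cmax/Tmax by
local optimization around the grid arg-max, AUC by adaptive quadrature,
and the half-life by root finding.  Two definitional choices matter:

* **Half-life** is *operational*: the first time after Tmax, measured
  from dosing, at which the central amount falls to half of Cmax.  For
  the benchmark parameter set this evaluates to 6.1715 h, whereas the
  terminal log-linear half-life $\ln 2 / \lambda_1$ would be 3.63 h;
  the operational definition is the one consistent with the benchmark
  tables this package reproduces, and it is the only one the code
  reports.
* **Default horizon and AUC window** are 40 h.  The benchmark AUC
  1.19933 equals the closed-form infinite-horizon exposure
  $\text{dose}/k_{el} = 1.2$ minus the tail $1.405\,e^{-0.190983\,T}$
  evaluated at $T = 40$ h (the tests verify this identity), which is
  how the default was fixed.
* **Tmax** is reported at the refined optimum of the interpolant.  For
  the uncoupled benchmark this is 1.7216 h; tabulated reference values
  (1.7292) were evidently read off a coarser grid and differ by ~0.4%,
  so comparisons against them use a 1% relative tolerance.

Degenerate analytic cases: the two hybrid constants are always distinct
for positive rates, and `k_abs = k_pc` merely cancels the third
exponential's coefficient algebraically (the benchmark drug X exercises
this).  If `k_abs` coincides with a hybrid constant, the closed form is
evaluated through the matrix exponential of the 3-compartment system
instead of the ill-conditioned coefficient formula.

## Two-stage estimation

Estimating all 16 rate constants plus the 8 interaction coefficients
jointly from sparse clinical sampling is hopeless, so the estimator is
hierarchical:

1. **Stage 1** (`fit_monotherapy()`): each drug's four rates and its
   apparent central volume are fitted to its *single-administration*
   curve by multi-start Levenberg–Marquardt on the closed-form
   solution, with log-parameterization enforcing positivity.  The
   tri-exponential is subject to the classic flip-flop ambiguity;
   among equal-SSE solutions the fit with the smallest absorption rate
   is returned (absorption-rate-limited convention).  When the fastest
   hybrid exponent has decayed before the first sample, a genuine
   equal-SSE ridge exists in (k_cp, k_pc, k_el, Vc); the fitted curve
   is then still exact but individual ridge members are not
   identified, which is why the full two-stage fit anchors each
   subject's stage 2 to that subject's own stage-1 solution rather
   than to parameters averaged across subjects.
2. **Stage 2** (`fit_interactions()`): with stage-1 rates fixed, the
   eight interaction coefficients W are estimated from the
   *combined-administration* central-amount series of both drugs by
   minimizing
   $z = \mathrm{SSE}_x + \mathrm{SSE}_y + \lambda\, \|W\|_2^2$,
   where each SSE term is the **mean** squared deviation at the
   observation times and the penalty is a plain sum of squares
   (no square root).

### Constraints

Every effective rate must stay non-negative, which bounds each
coefficient below by `-rate / (max driving amount)`.  The unobservable
driving amounts are replaced by practical surrogates: the partner's
initial dose for gut- and peripheral-driven couplings (an amount can
never exceed the dose) and the maximum *observed* central amount for
central-driven ones.  These lower bounds are always strictly negative,
so W = 0 is always feasible.  The rate constraints give no upper
bounds; the search box is closed with `upper = 10 |lower|`
(configurable).  During the search, candidates whose effective rates
are driven negative beyond the practical bounds can make the ODE stiff
to the point of failure; such candidates receive a large penalty value
and the optimizer moves on.

### The optimizer

The stage-2 objective is non-convex and the model is solved
numerically, so a gradient-free global method is used: a
constriction-coefficient particle swarm (inertia 0.7298, cognitive =
social = 1.49618, positions clamped to the box, one particle seeded at
W = 0), followed by a bounded quasi-Newton polish (L-BFGS-B) from the
swarm best.  Defaults are 30 particles and up to 150 iterations with
early stopping after 30 stalled iterations; doubling both changes the
estimates by under 1e-5, so the defaults are converged for this
problem class.  The seed is mandatory and the run is bit-reproducible;
the swarm draws never touch the caller's RNG state.

### The scale of the objective and the meaning of lambda

The penalty competes with the SSE terms, so the amount unit of the
observed series decides how strong a given $\lambda$ is.  On the
canonical 10^3 mg scale the SSE curvature with respect to W is of
order 10^-3–10^-2, and $\lambda = 0.6$ would annihilate every
estimate.  The objective therefore evaluates the SSE terms on the
**mg** scale (`pk_observations(scale = "mg")`, the default used by the
fitting routines), where the curvature is of order 10^3 and
$\lambda$ in [0.1, 1] acts as the mild stabilizer a regularized fit
intends, leaving well-identified couplings essentially unshrunk.  A
numerical scan of intermediate scales showed shrinkage is monotone
toward zero everywhere — there is no scale on which increasing
$\lambda$ *raises* an estimate — so reference values that show such a
rise cannot be reproduced by this objective; `lambda_scan()` reports
what the estimator actually does (a flat profile over {0.1, 0.3, 0.6,
0.9} under the default scale).  $\lambda = 0.6$ is the package
default; `lambda_scan()` exposes the sensitivity so users can judge
stability on their own data.

### Uncertainty

`bootstrap_fit()` treats the replicate dataset as the resampling unit:
each bootstrap draw selects a dataset with replacement and its
statistic is the stage-2 estimate refitted on that dataset (memoised,
so each dataset is fitted once).  The bootstrap distribution is thus
the sampling distribution of a single-dataset estimate and the
percentile CI reflects between-dataset variability — the
interpretation consistent with the CI widths the reference tables
print.  The optional p-value is the two-sided percentile position of a
user-supplied null value (e.g. the generating parameters).

`ablation_study()` refits under four nested masks — all eight
coefficients free; absorption couplings pinned to zero; elimination
couplings pinned; both pinned — and ranks them by R² and the
least-squares AIC $n \ln(\mathrm{SSE}/n) + 2k$ with $k$ the number of
free coefficients (the form available when only an SSE, not a
likelihood, is defined).

### Interaction-effect summaries

The fractional modification of a rate by its coupling is
$g \cdot \text{driving amount} / \text{baseline rate}$.
`interaction_effect_max()` evaluates it at the maximum driving amount
(the dose, for gut-driven couplings); `interaction_effect_at_time()`
reports either the instantaneous value at $t$ or its running mean over
$[0, t]$.  The time-averaged mode is the default because summaries "at
2, 6 and 12 h" of a monotonically decaying driver are most naturally
read as averages; both modes are exposed since the convention is not
universal.

## The synthetic-data generator

`make_scenario()` pins the two benchmark parameter sets; `add_noise()`
and `make_dataset()` generate replicate observation sets.  The
observation model is zero-mean Gaussian noise at each sampling time
with standard deviation `sd_frac` × amount (proportional, the
default), truncated at zero.  The proportional reading of "noise
scaled to the amount" is used because a constant sd of 0.1 on curves
peaking at 0.165 would drown the signal entirely; an additive mode is
available for sensitivity checks.  Truncation rather than resampling
keeps the model simple; at `sd_frac = 0.1` the induced mean bias is
below 1% for amounts above 0.02, which the tests verify empirically.

Two sampling grids appear in the package's own studies:

* dataset emulation of clinical designs uses the 13-point single-dose
  schedule 0.25–12 h (the generator default);
* the noisy-replicate *recovery* studies (and the acceptance script)
  sample at 0.2-h spacing over (0, 12] h, 60 points per drug.  The
  recovery study is simulation-based and not bound to a clinical
  schedule, and the between-replicate precision implied by the
  reference tables requires sampling well beyond 13 points; with the
  dense grid the per-dataset sd of the absorption-coupling estimate is
  about 0.03 at 10% noise.

What the generator does *not* emulate: between-subject variability of
the rate constants (replicates share one true curve and differ only in
measurement noise), assay limits of quantification, and dosing-time
deviations.  Passing the recovery tests therefore demonstrates that
the estimator inverts its own observation model, not that it is robust
to population heterogeneity.

The synthetic metoprolol/captopril scenario
(`make_scenario("metcap_synthetic")`) is a *stand-in* built from
published fitted parameters (50 mg doses, a shared Vc of 4163.137 ml,
all eight couplings active); it exercises the full two-stage pipeline
end to end, with its generation noise (8%) chosen so the resulting fit
quality sits at the R² ≈ 0.9 level the original analysis reports.  Its
rate constants are taken at face value in h^-1: the source table
annotates them as 10^-3 h^-1, which is kinetically incompatible with
12-hour sampling, and the effect ratios quoted from it are unit-free.
It is generated data, not clinical measurements, and conclusions about
the real drug pair should not be drawn from it.

## Problem sizes used by the shipped studies

The test suite runs the recovery study at 25 replicates, the lambda
scan at 8 replicates per grid point, the bootstrap at 200 draws over
the 25 replicate fits, the ablation at a single low-noise dataset, and
the end-to-end pipeline at 4 subjects; `scripts/acceptance.R` runs the
recovery study at the full 100 replicates.  These sizes are the
package's reporting choices; all are parameters of the exported
functions.

## Known limitations

* Single oral dose per drug, two drugs, linear kinetics only; no
  multi-dose regimens, no Michaelis–Menten saturation, no
  transporter/enzyme submodels.
* Stage 1 inherits the identifiability limits of tri-exponential
  fitting discussed above; with very fast distribution kinetics the
  apparent central volume is determined only up to the equal-SSE
  ridge.
* The stage-2 estimator is a least-squares point estimator; its
  finite-sample bias under proportional noise is of order the noise
  variance (about −0.005 on a coupling of 0.4 at 10% noise in the
  shipped study), and the bootstrap quantifies spread, not this bias.
* The regularization path of the mg-scale objective is deliberately
  mild; users wanting strong shrinkage should raise `lambda` by orders
  of magnitude, not by decimals.
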