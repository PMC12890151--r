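# coupledpk

Quantifying drug–drug interactions with a linearly coupled
two-compartment oral pharmacokinetic model.

When two oral drugs are co-administered, each can change how fast the
other is absorbed, distributed and eliminated.  Classical compartmental
PK models cannot express this: their rate constants are fixed numbers.
`coupledpk` implements a model in which every rate constant of drug X
is modified linearly by drug Y's current amount in a driving
compartment (and vice versa),

    dx0/dt = -(a_abs + g_abs * y0) * x0
    dx1/dt =  (a_abs + g_abs * y0) * x0 - (a_cp + g_cp * y1) * x1
             + (a_pc + g_pc * y2) * x2 - (a_el + g_el * y1) * x1
    dx2/dt =  (a_cp + g_cp * y1) * x1 - (a_pc + g_pc * y2) * x2

where `x0, x1, x2` are gut, central and peripheral amounts, `a_*` are
the drug's own rate constants (h⁻¹) and `g_*` are interaction
coefficients (10³/(mg·h)); a negative `g` means the partner inhibits
that process, a positive one means promotion.  The package is aimed at
PK modellers and methods researchers who need to *estimate* such
couplings from standard single- and combined-administration
concentration–time data.

It provides:

* forward simulation (`pk_simulate`) with strict mass balance, a
  compiled right-hand side, and a closed-form uncoupled solution
  (`analytic_uncoupled`) as an independent oracle;
* PK summary metrics (`pk_metrics`: Cmax, Tmax, AUC, operational
  half-life) and interaction-coefficient sweep tables
  (`metrics_table`);
* a hierarchical two-stage estimator: per-drug monotherapy fits of the
  rates and apparent central volume (`fit_monotherapy`), then a
  constrained, L2-regularized particle-swarm fit of the eight
  interaction coefficients (`fit_interactions`), wrapped for full
  studies in `fit_coupled()`, which returns a model object with
  `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
  `simulate` methods;
* validation tooling: `lambda_scan`, `bootstrap_fit`,
  `ablation_study`, and effect summaries
  (`interaction_effect_max`, `interaction_effect_at_time`);
* a seeded synthetic-data generator (`make_scenario`, `add_noise`,
  `make_dataset`) and long-format CSV/XLSX I/O
  (`read_observations`, `write_results`), plus a thin CLI at
  `inst/cli/coupledpk.R`.

## Worked example

Simulate the benchmark pair (drug X: dose 0.6 ×10³ mg, all rates
0.5 h⁻¹; drug Y: dose 1 ×10³ mg, rates 0.6/0.5/0.4/0.3 h⁻¹) with drug Y
promoting drug X's absorption, and summarize drug X's exposure:

```r
library(coupledpk)

sys  <- make_scenario("table1", x.g_abs = 0.4)
traj <- pk_simulate(sys, horizon = 40, step = 0.001)
pk_metrics(traj, "x")
#>        cmax     tmax      auc    thalf auc_window
#> 1 0.2029415 1.160837 1.199412 4.515914         40
```

Relative to the uncoupled case (Cmax 0.16496 at Tmax 1.7216 h,
half-life 6.1715 h), the positive absorption coupling raises the peak
to 0.2029 ×10³ mg, pulls it forward to 1.16 h and shortens the
operational half-life to 4.52 h, while the AUC barely moves — faster
absorption changes the shape of exposure, not its total.

Recover the coupling from data: sample the combined-administration
curves, then fit the eight interaction coefficients with the stage-1
rates fixed:

```r
d   <- add_noise(traj, noise_spec(sd_frac = 0, n_reps = 1, seed = 1,
                                  times = seq(0.2, 12, by = 0.2)))[[1]]
obs <- pk_observations(d$time, d$x_obs * 1000, d$time, d$y_obs * 1000)
fit_interactions(obs, make_scenario("table1"), lambda = 0,
                 control = pso_control(seed = 1))
#> Stage-2 interaction fit (lambda = 0 )
#>     x.g_abs      x.g_cp      x.g_pc      x.g_el     y.g_abs      y.g_cp
#>  4.0000e-01 -1.6046e-06 -2.1734e-06  8.6680e-08  1.0289e-06  2.1150e-06
#>      y.g_pc      y.g_el
#>  7.2066e-06  1.1981e-06
#> z = 3.04883e-09  R^2(X) = 1.0000  R^2(Y) = 1.0000  AIC = -2420.20
```

The generating coefficient (`x.g_abs = 0.4`) is recovered to 5 decimal
places and the seven inactive couplings stay at zero.  With measurement
noise the single-dataset estimates scatter (the objective has soft,
correlated directions) and the replicate mean is the meaningful
quantity; `bootstrap_fit()` quantifies that spread.

Translate a fitted coefficient into pharmacology: with the published
metoprolol/captopril estimates, captopril's maximum inhibitory effect
on metoprolol's absorption rate is

```r
interaction_effect_max(-1.270, 0.05, 0.205)
#> [1] -30.97561
```

i.e. at the moment of dosing, 50 mg of captopril in the gut slows
metoprolol's absorption by about 31%; the effect decays as captopril is
absorbed (`interaction_effect_at_time()` gives the time-resolved
profile).

The methods vignette (`vignettes/coupled-pk-methods.Rmd`) documents the
model, the estimator, the regularization-scale analysis and the
generator's assumptions in detail.

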