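# Shared fixtures, built in code.

# Benchmark doses/rates used across the tests (drug X all-0.5 rates,
# drug Y 0.6/0.5/0.4/0.3).
table1 <- function(...) make_scenario("table1", ...)

# Closed-form central amount of the benchmark drug X:
# 0.268328 (e^{-0.190983 t} - e^{-1.309017 t})
table1_x_curve <- function(t) {
  0.2683281573 * (exp(-0.1909830056 * t) - exp(-1.3090169944 * t))
}

# Dense sampling grid used by the noisy-recovery studies (see the
# methods vignette for why this is denser than the clinical schedule).
recovery_times <- seq(0.2, 12, by = 0.2)

# Replicate datasets for the alpha-abs = 0.4 recovery scenario.
recovery_datasets <- function(n_reps, seed, sd_frac = 0.1) {
  traj <- pk_simulate(make_scenario(x.g_abs = 0.4), horizon = 12.5,
                      step = 0.005)
  add_noise(traj, noise_spec(sd_frac = sd_frac, n_reps = n_reps,
                             seed = seed, times = recovery_times))
}

# Quick PSO settings for unit tests (acceptance tests use defaults).
quick_ctl <- function(seed) pso_control(swarm = 24, maxit = 100,
                                        patience = 25, seed = seed)
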