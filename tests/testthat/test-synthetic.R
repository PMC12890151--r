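test_that("scenario overrides change only the requested coefficient", {
  base <- make_scenario()
  expect_equal(unname(base$drug_x$rates), rep(0.5, 4))
  expect_equal(unname(base$drug_y$rates), c(0.6, 0.5, 0.4, 0.3))
  expect_equal(c(base$drug_x$dose, base$drug_y$dose), c(0.6, 1.0))

  mod <- make_scenario(x.g_abs = 0.4)
  expect_equal(mod$drug_x$interactions[["g_abs"]], 0.4)
  mod$drug_x$interactions[["g_abs"]] <- 0
  expect_equal(mod, base)

  # infeasible override is rejected with the violated bound named
  expect_error(make_scenario(x.g_abs = -0.6), "x.g_abs > -0.5")
  expect_error(make_scenario(bogus = 1), "unknown interaction")
})

test_that("noise generation is seeded, truncated and leaves the RNG alone", {
  traj <- pk_simulate(table1(), horizon = 12.5, step = 0.01)
  ns0 <- noise_spec(sd_frac = 0, n_reps = 3, seed = 5)
  reps0 <- add_noise(traj, ns0)
  expect_length(reps0, 3L)
  expect_identical(reps0[[1]], reps0[[3]])     # zero noise: all equal
  cen <- coupledpk:::.sample_centrals(traj, ns0$times)
  expect_equal(reps0[[1]]$x_obs, cen$x)

  ns <- noise_spec(sd_frac = 0.1, n_reps = 2, seed = 42)
  set.seed(999); before <- stats::runif(1)
  set.seed(999)
  r1 <- add_noise(traj, ns)
  expect_identical(stats::runif(1), before)     # RNG state preserved
  r2 <- add_noise(traj, ns)
  expect_identical(r1, r2)                      # same seed, same draws
  expect_true(all(r1[[1]]$x_obs >= 0))
  expect_error(noise_spec(sd_frac = -1, seed = 1), "non-negative")
  expect_error(noise_spec(sd_frac = 0.1), "seed")
})

test_that("empirical noise sd tracks 0.1 x amount", {
  traj <- pk_simulate(table1(), horizon = 12.5, step = 0.01)
  times <- c(0.5, 1.5, 4)
  reps <- add_noise(traj, noise_spec(sd_frac = 0.1, n_reps = 5000,
                                     seed = 31, times = times))
  xs <- vapply(reps, function(r) r$x_obs, numeric(3L))
  cen <- coupledpk:::.sample_centrals(traj, times)
  emp_sd <- apply(xs, 1L, sd)
  expect_lt(max(abs(emp_sd / (0.1 * cen$x) - 1)), 0.05)
  # truncation bias is negligible at these amounts
  expect_lt(max(abs(rowMeans(xs) / cen$x - 1)), 0.01)
})

test_that("combined regimen with no coupling equals the single regimens", {
  ns <- noise_spec(sd_frac = 0, n_reps = 1, seed = 1)
  both <- make_dataset(table1(), "combined", ns)
  sx <- make_dataset(table1(), "single-x", ns)
  sy <- make_dataset(table1(), "single-y", ns)
  expect_setequal(unique(sx$drug), "X")
  expect_setequal(unique(sy$drug), "Y")
  expect_equal(both$concentration[both$drug == "X"], sx$concentration,
               tolerance = 1e-9)
  expect_equal(both$concentration[both$drug == "Y"], sy$concentration,
               tolerance = 1e-9)
  expect_equal(unique(both$regimen), "combined")
  expect_equal(unique(sx$regimen), "single")
})

test_that("datasets survive a write/read round trip", {
  ds <- make_dataset(make_scenario(x.g_abs = 0.4), "combined",
                     noise_spec(sd_frac = 0.1, n_reps = 2, seed = 3))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(ds, path, row.names = FALSE)
  back <- read_observations(path)
  expect_equal(nrow(back), nrow(ds))
  expect_equal(back$conc, ds$concentration, tolerance = 1e-12)
  expect_equal(back$dose, ds$dose_mg / 1000, tolerance = 1e-12)
  unlink(path)
})
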