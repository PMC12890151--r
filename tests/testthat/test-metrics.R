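# Metric tests run on a 0.01-h output grid, which keeps them fast; the
# acceptance suite re-verifies the printed benchmark values on the
# 0.001-h production grid.

traj40 <- pk_simulate(table1(), horizon = 40, step = 0.01)

test_that("peak location agrees with the closed-form stationary point", {
  pk <- pk_peak(traj40, "x")
  l1 <- 0.1909830056; l2 <- 1.3090169944
  t_star <- log(l2 / l1) / (l2 - l1)
  expect_equal(pk[["tmax"]], t_star, tolerance = 1e-5)
  expect_equal(pk[["cmax"]], table1_x_curve(t_star), tolerance = 1e-7)
})

test_that("AUC matches the closed-form mass-balance identity", {
  # AUC over [0,T] = dose/k_el - tail, tail = 1.40498 exp(-lambda1 T)
  for (T in c(20, 40)) {
    expected <- 1.2 - (0.2683281573 / 0.1909830056) *
      exp(-0.1909830056 * T) + (0.2683281573 / 1.3090169944) *
      exp(-1.3090169944 * T)
    expect_equal(pk_auc(traj40, "x", c(0, T)), expected,
                 tolerance = 1e-6)
  }
  expect_error(pk_auc(traj40, "x", c(0, 50)), "exceeds")
})

test_that("half-life agrees with root-finding on the analytic curve", {
  th <- pk_half_life(traj40, "x")
  pk <- pk_peak(traj40, "x")
  oracle <- uniroot(function(t) table1_x_curve(t) - pk[["cmax"]] / 2,
                    c(pk[["tmax"]], 40), tol = 1e-12)$root
  expect_equal(th, oracle, tolerance = 1e-6)
  # invariant to output-grid refinement
  th2 <- pk_half_life(pk_simulate(table1(), horizon = 40, step = 0.02),
                      "x")
  expect_lt(abs(th - th2), 1e-3)
})

test_that("degenerate curves are flagged, not silently numbered", {
  # monotone decreasing curve (bolus-like): peak at t = 0
  fake <- data.frame(time = seq(0, 10, 0.1),
                     x_cen = exp(-seq(0, 10, 0.1)))
  for (cn in c("x_gut", "x_per", "x_elim", "y_gut", "y_cen", "y_per",
               "y_elim"))
    fake[[cn]] <- 0
  class(fake) <- c("pk_trajectory", "data.frame")
  expect_equal(pk_peak(fake, "x")[["tmax"]], 0)

  zero <- fake; zero$x_cen <- 0
  expect_warning(pz <- pk_peak(zero, "x"), "zero")
  expect_equal(unname(pz), c(0, 0))
  w <- testthat::capture_warnings(th0 <- pk_half_life(zero, "x"))
  expect_true(is.na(th0))
  expect_true(any(grepl("undefined", w)))

  # window too short to fall to Cmax/2
  short <- pk_simulate(table1(), horizon = 3, step = 0.01)
  expect_warning(expect_true(is.na(pk_half_life(short, "x"))),
                 "never falls")
})

test_that("absorption-interaction sweep reproduces the benchmark trends", {
  grid <- c(-0.4, -0.2, 0, 0.2, 0.4, 2)
  tab <- metrics_table(table1(), "x.g_abs", grid, step = 0.01)
  expect_true(all(tab$feasible))
  expect_true(all(diff(tab$cmax) > 0))    # Cmax increases with g_abs
  expect_true(all(diff(tab$tmax) < 0))    # peak comes earlier
  expect_true(all(diff(tab$thalf) < 0))   # half-life shortens
  # the zero row equals the uncoupled metrics
  m0 <- pk_metrics(traj40, "x")
  expect_equal(tab$cmax[tab$sweep_value == 0], m0$cmax, tolerance = 1e-9)
  expect_equal(tab$auc[tab$sweep_value == 0], m0$auc, tolerance = 1e-9)
})

test_that("elimination-interaction sweep shortens the half-life", {
  tab <- metrics_table(table1(), "x.g_el", c(-0.5, 0, 0.5, 1),
                       step = 0.01)
  expect_true(all(diff(tab$thalf) < 0))
  expect_true(all(diff(tab$cmax) < 0))    # faster elimination, lower peak
})

test_that("infeasible sweep values are flagged rather than dropped", {
  tab <- metrics_table(table1(), "x.g_abs", c(-0.6, 0), step = 0.05)
  expect_equal(nrow(tab), 2L)
  expect_false(tab$feasible[1])
  expect_true(is.na(tab$cmax[1]))
  expect_true(tab$feasible[2])
})
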