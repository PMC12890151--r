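test_that("coupled_rhs reproduces hand-computed derivatives", {
  sys <- table1()
  state <- c(0.6, 0, 0, 0, 1, 0, 0, 0)
  d <- coupled_rhs(state, sys)
  expect_equal(d[1], -0.5 * 0.6)          # gut drain of X
  expect_equal(d[5], -0.6 * 1.0)          # gut drain of Y
  expect_equal(d[2], 0.30)                # all absorbed flux enters central
  expect_equal(sum(d[1:4]), 0)            # per-drug component sum is zero
  expect_equal(sum(d[5:8]), 0)

  # absorption coupling driven by the partner's gut amount
  d2 <- coupled_rhs(state, make_scenario(x.g_abs = 0.4))
  expect_equal(d2[1], -(0.5 + 0.4 * 1.0) * 0.6)

  expect_equal(coupled_rhs(rep(0, 8), sys), rep(0, 8))
  expect_error(coupled_rhs(c(NA, rep(0, 7)), sys), "finite")
})

test_that("compiled integrator agrees with the pure-R right-hand side", {
  sys <- make_scenario(x.g_abs = 0.3, y.g_el = -0.2, x.g_cp = 0.5)
  times <- seq(0, 10, by = 0.5)
  ref <- deSolve::lsoda(
    y = c(0.6, 0, 0, 0, 1, 0, 0, 0), times = times,
    func = function(t, y, p) list(coupled_rhs(y, sys)),
    rtol = 1e-9, atol = 1e-12)
  traj <- pk_simulate(sys, horizon = 10, step = 0.5)
  expect_lt(max(abs(as.matrix(traj[, -1]) - ref[, -1])), 1e-8)
})

test_that("mass is conserved and zero dose gives a zero trajectory", {
  traj <- pk_simulate(table1(), horizon = 40, step = 0.05)
  expect_lt(max(abs(traj$x_gut + traj$x_cen + traj$x_per + traj$x_elim -
                      0.6)) / 0.6, 1e-8)
  expect_lt(max(abs(traj$y_gut + traj$y_cen + traj$y_per + traj$y_elim -
                      1.0)), 1e-8)
  expect_equal(unname(unlist(traj[1, -1])),
               c(0.6, 0, 0, 0, 1, 0, 0, 0))   # dosing initial condition

  zsys <- table1(); zsys$drug_x$dose <- 0; zsys$drug_y$dose <- 0
  ztraj <- pk_simulate(zsys, horizon = 5, step = 0.5)
  expect_true(all(as.matrix(ztraj[, -1]) == 0))
})

test_that("gut amounts drain monotonically under positive effective rates", {
  traj <- pk_simulate(make_scenario(x.g_abs = 0.4, y.g_abs = -0.5),
                      horizon = 20, step = 0.05)
  expect_true(all(diff(traj$x_gut) <= 1e-12))
  expect_true(all(diff(traj$y_gut) <= 1e-12))
  expect_true(min(as.matrix(traj[, -1])) > -1e-10)
})

test_that("analytic solution: hybrid constants, initial value, degeneracy", {
  an <- analytic_uncoupled(c(k_abs = 0.5, k_cp = 0.5, k_pc = 0.5,
                             k_el = 0.5), 0.6, c(0, 1, 2))
  lam <- attr(an, "lambda")
  expect_equal(unname(lam), c(0.190983005625, 1.309016994375),
               tolerance = 1e-10)
  expect_equal(an[1], 0)
  expect_equal(as.numeric(an[2:3]), table1_x_curve(c(1, 2)),
               tolerance = 1e-10)

  # k_abs equal to a hybrid constant: limit path must agree with the
  # numeric integrator
  rates <- c(k_abs = 0.110102051443, k_cp = 0.5, k_pc = 0.4, k_el = 0.3)
  b <- 0.5 + 0.4 + 0.3
  l1 <- (b - sqrt(b^2 - 4 * 0.4 * 0.3)) / 2
  rates[["k_abs"]] <- l1   # exact degeneracy
  tt <- seq(0, 20, by = 0.5)
  an2 <- analytic_uncoupled(rates, 1, tt)
  sys <- coupled_system(
    drug_spec(1, rates[["k_abs"]], rates[["k_cp"]], rates[["k_pc"]],
              rates[["k_el"]]),
    drug_spec(0, 0.6, 0.5, 0.4, 0.3))
  num <- pk_simulate(sys, horizon = 20, step = 0.5)$x_cen
  expect_lt(max(abs(num - an2)), 1e-6)
})

test_that("uncoupled simulation matches the closed form within 1e-6", {
  traj <- pk_simulate(table1(), horizon = 40, step = 0.05)
  expect_lt(max(abs(traj$x_cen - table1_x_curve(traj$time))), 1e-6)
  an_y <- analytic_uncoupled(c(k_abs = 0.6, k_cp = 0.5, k_pc = 0.4,
                               k_el = 0.3), 1, traj$time)
  expect_lt(max(abs(traj$y_cen - an_y)), 1e-6)
})

test_that("swapping drug labels swaps the trajectories", {
  sys <- make_scenario(x.g_abs = 0.3, y.g_cp = 0.5, x.g_el = -0.4)
  a <- pk_simulate(sys, horizon = 10, step = 0.2)
  b <- pk_simulate(swap_drugs(sys), horizon = 10, step = 0.2)
  expect_lt(max(abs(as.matrix(a[, 2:5]) - as.matrix(b[, 6:9]))), 1e-12)
  expect_lt(max(abs(as.matrix(a[, 6:9]) - as.matrix(b[, 2:5]))), 1e-12)
})

test_that("mass balance holds across randomized feasible systems", {
  set.seed(20)
  for (i in 1:20) {
    rr <- function() stats::runif(4, 0.1, 2)
    rx <- rr(); ry <- rr()
    dx <- stats::runif(1, 0.2, 2); dy <- stats::runif(1, 0.2, 2)
    sys <- coupled_system(
      drug_spec(dx, rx[1], rx[2], rx[3], rx[4]),
      drug_spec(dy, ry[1], ry[2], ry[3], ry[4]))
    bounds <- coupledpk:::.feasibility_bounds(sys, horizon = 8)
    W <- stats::runif(8, 0.5 * bounds, 2 * abs(bounds))
    sys <- coupledpk:::.set_W(sys, W)
    traj <- pk_simulate(sys, horizon = 8, step = 0.2)
    tot_x <- rowSums(traj[, c("x_gut", "x_cen", "x_per", "x_elim")])
    tot_y <- rowSums(traj[, c("y_gut", "y_cen", "y_per", "y_elim")])
    expect_lt(max(abs(tot_x - dx)) / dx, 1e-8)
    expect_lt(max(abs(tot_y - dy)) / dy, 1e-8)
  }
})

test_that("concentration/amount conversion is exact and validated", {
  expect_equal(amount_from_concentration(0, 4000), 0)
  expect_equal(amount_from_concentration(1e-5, 4163.137), 0.04163137)
  amt <- c(0.01, 0.2, 0.15)
  expect_identical(
    amount_from_concentration(
      concentration_from_amount(amt, 4163.137), 4163.137), amt)
  # unit bookkeeping: 1 ng/ml in 1000 ml is 1e-6 mg = 1e-9 * 10^3 mg
  expect_equal(amount_from_concentration(1, 1000, unit = "ng/ml"), 1e-6)
  expect_error(amount_from_concentration(1, NULL), "v_central")
  expect_error(amount_from_concentration(-1, 100), "non-negative")
  expect_error(amount_from_concentration(1, 100, unit = "furlongs"),
               "unknown concentration unit")
})
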