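#' Right-hand side of the coupled PK ODE system
#'
#' Evaluates the time derivative of the 8-component state
#' `(x_gut, x_cen, x_per, x_elim, y_gut, y_cen, y_per, y_elim)` of the
#' linearly coupled two-compartment oral model.  Each effective rate is
#' `baseline + g * (partner amount in the driving compartment)`; the two
#' `*_elim` components accumulate the elimination flux so that each
#' drug's four components sum to its dose at all times.
#'
#' This is the reference R implementation; [pk_simulate()] integrates
#' the identical system through a compiled version for speed.
#'
#' @param state numeric length-8 state vector, ordered as above
#'   (amounts, 10^3 mg).
#' @param system a [coupled_system()].
#' @return Numeric length-8 derivative vector (10^3 mg/h).
#' @examples
#' sys <- make_scenario()
#' coupled_rhs(c(0.6, 0, 0, 0, 1, 0, 0, 0), sys)
#' @export
coupled_rhs <- function(state, system) {
  stopifnot(inherits(system, "coupled_system"))
  if (length(state) != 8L || !is.numeric(state) || any(!is.finite(state)))
    stop("'state' must be a finite numeric vector of length 8",
         call. = FALSE)
  rx <- system$drug_x$rates; gx <- system$drug_x$interactions
  ry <- system$drug_y$rates; gy <- system$drug_y$interactions
  x_gut <- state[1]; x_cen <- state[2]; x_per <- state[3]
  y_gut <- state[5]; y_cen <- state[6]; y_per <- state[7]

  ax_abs <- rx[["k_abs"]] + gx[["g_abs"]] * y_gut
  ax_cp  <- rx[["k_cp"]]  + gx[["g_cp"]]  * y_cen
  ax_pc  <- rx[["k_pc"]]  + gx[["g_pc"]]  * y_per
  ax_el  <- rx[["k_el"]]  + gx[["g_el"]]  * y_cen
  ay_abs <- ry[["k_abs"]] + gy[["g_abs"]] * x_gut
  ay_cp  <- ry[["k_cp"]]  + gy[["g_cp"]]  * x_cen
  ay_pc  <- ry[["k_pc"]]  + gy[["g_pc"]]  * x_per
  ay_el  <- ry[["k_el"]]  + gy[["g_el"]]  * x_cen

  c(-ax_abs * x_gut,
    ax_abs * x_gut - ax_cp * x_cen + ax_pc * x_per - ax_el * x_cen,
    ax_cp * x_cen - ax_pc * x_per,
    ax_el * x_cen,
    -ay_abs * y_gut,
    ay_abs * y_gut - ay_cp * y_cen + ay_pc * y_per - ay_el * y_cen,
    ay_cp * y_cen - ay_pc * y_per,
    ay_el * y_cen)
}

.state_names <- c("x_gut", "x_cen", "x_per", "x_elim",
                  "y_gut", "y_cen", "y_per", "y_elim")

# Low-level integrator shared by pk_simulate() and the estimation
# objective.  `times` must start at 0.  Returns the deSolve matrix.
.integrate_system <- function(system, times, rtol = 1e-9, atol = 1e-12) {
  y0 <- c(system$drug_x$dose, 0, 0, 0, system$drug_y$dose, 0, 0, 0)
  out <- deSolve::lsoda(y = y0, times = times, func = "cpk_derivs",
                        parms = unname(.system_parms(system)),
                        dllname = "coupledpk", initfunc = "cpk_init",
                        rtol = rtol, atol = atol, maxsteps = 50000L)
  if (attr(out, "istate")[1L] < 0 || any(!is.finite(out)))
    stop("ODE integration failed (non-finite trajectory or solver error); ",
         "check that the interaction coefficients keep all effective ",
         "rates non-negative", call. = FALSE)
  out
}

#' Simulate the coupled PK system
#'
#' Integrates the coupled ODE system from the dosing initial condition
#' `(dose, 0, 0, 0)` per drug with a stiff-capable adaptive solver
#' (`deSolve::lsoda`, relative tolerance 1e-9, absolute 1e-12) and
#' returns the amounts of both drugs in the gut, central and peripheral
#' compartments plus the cumulative eliminated amount on a dense output
#' grid.
#'
#' @param system a [coupled_system()].
#' @param horizon simulation end time, h (default 40).
#' @param step output grid spacing, h (default 0.001).  The solver's
#'   internal steps are adaptive; `step` only controls the stored grid,
#'   which downstream metrics interpolate.
#' @param rtol,atol solver tolerances.
#' @return A data frame of class `pk_trajectory` with columns `time`
#'   and the eight state amounts (`x_gut`, `x_cen`, `x_per`, `x_elim`,
#'   `y_gut`, `y_cen`, `y_per`, `y_elim`), all in 10^3 mg.
#' @examples
#' traj <- pk_simulate(make_scenario(), horizon = 12, step = 0.01)
#' head(traj)
#' @export
pk_simulate <- function(system, horizon = 40, step = 0.001,
                        rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(system, "coupled_system"))
  if (!is.numeric(horizon) || horizon <= 0)
    stop("'horizon' must be positive", call. = FALSE)
  if (!is.numeric(step) || step <= 0)
    stop("'step' must be positive", call. = FALSE)
  times <- seq(0, horizon, by = step)
  if (times[length(times)] < horizon)
    times <- c(times, horizon)
  out <- .integrate_system(system, times, rtol = rtol, atol = atol)
  traj <- as.data.frame(out)
  names(traj) <- c("time", .state_names)
  attr(traj, "system") <- system
  class(traj) <- c("pk_trajectory", "data.frame")
  traj
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf(
    "Coupled PK trajectory: %d time points on [0, %g] h (amounts, 10^3 mg)\n",
    nrow(x), max(x$time)))
  print(utils::head(as.data.frame(x), 4L))
  cat("...\n")
  invisible(x)
}

#' @param y which drug(s) to draw, `"x"`, `"y"` or `"both"`.
#' @rdname pk_simulate
#' @export
plot.pk_trajectory <- function(x, y = c("both", "x", "y"), ...) {
  y <- match.arg(y)
  cols <- switch(y, x = .state_names[1:4], y = .state_names[5:8],
                 both = .state_names)
  graphics::matplot(x$time, as.matrix(x[cols]), type = "l", lty = 1,
                    xlab = "time (h)", ylab = "amount (10^3 mg)", ...)
  graphics::legend("topright", legend = cols, col = seq_along(cols),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

# Central-compartment amounts of one drug at given times (fast path for
# the estimation objective: integrates only at the requested times,
# with looser tolerances suited to repeated calls inside an optimizer).
.central_at <- function(system, times, drug = c("x", "y"),
                        rtol = 1e-7, atol = 1e-10) {
  drug <- match.arg(drug)
  tt <- sort(unique(c(0, times)))
  out <- .integrate_system(system, tt, rtol = rtol, atol = atol)
  col <- if (drug == "x") 3L else 7L  # +1 for the time column
  out[match(times, tt), col]
}

# Both drugs' central series at (possibly different) time grids in one
# integration.
.central_both <- function(system, times_x, times_y,
                          rtol = 1e-7, atol = 1e-10) {
  tt <- sort(unique(c(0, times_x, times_y)))
  out <- .integrate_system(system, tt, rtol = rtol, atol = atol)
  list(x = out[match(times_x, tt), 3L],
       y = out[match(times_y, tt), 7L])
}
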