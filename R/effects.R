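#' Maximum fractional effect of one drug on a partner rate process
#'
#' The linear coupling modifies a baseline rate as
#' `rate_eff = rate + g * driving_amount`, so the largest fractional
#' change of the rate over the observable range is
#' `g * max(driving amount) / rate`, expressed in percent.  The sign
#' carries the direction: negative values are inhibition, positive
#' promotion.
#'
#' @param g interaction coefficient, 10^3/(mg h).
#' @param amount maximum driving amount, 10^3 mg (for a gut-driven
#'   coupling this is the partner's initial dose).
#' @param baseline baseline rate constant, h^-1; must be positive.
#' @return Signed percent effect.
#' @examples
#' interaction_effect_max(-1.270, 0.05, 0.205)  # about -31%
#' @export
interaction_effect_max <- function(g, amount, baseline) {
  if (any(baseline <= 0))
    stop("'baseline' rate must be positive", call. = FALSE)
  100 * g * amount / baseline
}

# Driving compartment of each interaction coefficient: which partner
# column of the trajectory modifies the rate.
.DRIVER_COLS <- c(x.g_abs = "y_gut", x.g_cp = "y_cen", x.g_pc = "y_per",
                  x.g_el = "y_cen", y.g_abs = "x_gut", y.g_cp = "x_cen",
                  y.g_pc = "x_per", y.g_el = "x_cen")

#' Time-resolved fractional effect of a coupling term
#'
#' Evaluates the percent modification of a rate constant by its
#' coupling term at (or up to) a given time: instantaneous mode returns
#' `100 * g * driver(t) / baseline`; time-averaged mode (the default)
#' returns the mean of that quantity over `[0, t]`.  The driving
#' amount is read from the simulated trajectory of the fitted system.
#'
#' @param traj a `pk_trajectory` covering `t`, simulated from the
#'   system whose coefficients are being interrogated (its `system`
#'   attribute supplies `g` and the baseline rate).
#' @param which one of `"x.g_abs"`, `"x.g_cp"`, `"x.g_pc"`, `"x.g_el"`,
#'   `"y.g_abs"`, `"y.g_cp"`, `"y.g_pc"`, `"y.g_el"`.
#' @param t time, h.
#' @param mode `"averaged"` or `"instantaneous"`.
#' @return Signed percent effect.
#' @examples
#' sys <- make_scenario("metcap_synthetic")
#' traj <- pk_simulate(sys, horizon = 12, step = 0.01)
#' interaction_effect_at_time(traj, "x.g_abs", t = 2)
#' @export
interaction_effect_at_time <- function(traj, which = .W_NAMES, t,
                                       mode = c("averaged",
                                                "instantaneous")) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  system <- attr(traj, "system")
  if (is.null(system))
    stop("trajectory carries no system attribute; simulate it with ",
         "pk_simulate()", call. = FALSE)
  if (t > max(traj$time) + 1e-9 || t < 0)
    stop("'t' must lie within the trajectory span", call. = FALSE)
  g <- .system_W(system)[[which]]
  drug <- substr(which, 1L, 1L)
  rate_name <- c(g_abs = "k_abs", g_cp = "k_cp", g_pc = "k_pc",
                 g_el = "k_el")[[substr(which, 3L, nchar(which))]]
  baseline <- if (drug == "x") system$drug_x$rates[[rate_name]]
              else system$drug_y$rates[[rate_name]]
  f <- stats::splinefun(traj$time, traj[[.DRIVER_COLS[[which]]]],
                        method = "natural")
  driver <- if (mode == "instantaneous" || t == 0) f(t)
            else stats::integrate(f, 0, t, subdivisions = 1000L,
                                  rel.tol = 1e-9)$value / t
  interaction_effect_max(g, driver, baseline)
}
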