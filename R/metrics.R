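# Interpolant of one drug's central-compartment amount on the stored
# dense grid.  Natural cubic spline; with the default 0.001 h output
# step its error is far below the solver tolerance.
.central_fun <- function(traj, drug = c("x", "y")) {
  drug <- match.arg(drug)
  col <- if (drug == "x") "x_cen" else "y_cen"
  stats::splinefun(traj$time, traj[[col]], method = "natural")
}

#' Peak central amount and its time
#'
#' Finds Cmax and Tmax of one drug's central-compartment curve.  The
#' arg-max is refined by a local search on the spline interpolant of the
#' dense solution, not read off the raw output grid.
#'
#' @param traj a `pk_trajectory` from [pk_simulate()].
#' @param drug `"x"` or `"y"`.
#' @return Named numeric vector `c(cmax, tmax)` (10^3 mg, h).
#' @examples
#' traj <- pk_simulate(make_scenario(), horizon = 20, step = 0.01)
#' pk_peak(traj, "x")
#' @export
pk_peak <- function(traj, drug = c("x", "y")) {
  drug <- match.arg(drug)
  col <- if (drug == "x") "x_cen" else "y_cen"
  v <- traj[[col]]
  if (all(v <= 0)) {
    warning("central-compartment curve is identically zero")
    return(c(cmax = 0, tmax = 0))
  }
  i <- which.max(v)
  if (i == 1L)  # curve decreasing from t = 0 (e.g. bolus into central)
    return(c(cmax = v[1L], tmax = traj$time[1L]))
  f <- .central_fun(traj, drug)
  lo <- traj$time[max(1L, i - 2L)]
  hi <- traj$time[min(nrow(traj), i + 2L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  c(cmax = opt$objective, tmax = opt$maximum)
}

#' Area under the central-amount curve
#'
#' Integrates one drug's central-compartment amount over a stated
#' window by adaptive quadrature on the spline interpolant of the dense
#' solution.
#'
#' @inheritParams pk_peak
#' @param window integration window `c(0, T)` in h; must lie within the
#'   trajectory span.
#' @return AUC in 10^3 mg h.
#' @export
pk_auc <- function(traj, drug = c("x", "y"), window = c(0, 40)) {
  drug <- match.arg(drug)
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] > window[1])
  if (window[2] > max(traj$time) + 1e-9)
    stop("AUC window [", window[1], ", ", window[2],
         "] exceeds the trajectory span [0, ", max(traj$time), "]",
         call. = FALSE)
  f <- .central_fun(traj, drug)
  stats::integrate(f, window[1], window[2], subdivisions = 2000L,
                   rel.tol = 1e-10, abs.tol = 1e-12)$value
}

#' Time to half the peak central amount
#'
#' Operational half-life: the first time after Tmax, measured from
#' dosing (t = 0), at which the central amount falls to half of Cmax.
#' Located by root-finding on the spline interpolant.  Note this is not
#' the terminal log-linear half-life `ln 2 / lambda_1`; the two differ
#' whenever absorption and distribution still shape the post-peak curve
#' (see the methods vignette).
#'
#' @inheritParams pk_peak
#' @return Half-life in h, or `NA` with a warning if the curve never
#'   falls to Cmax/2 within the trajectory window.
#' @export
pk_half_life <- function(traj, drug = c("x", "y")) {
  drug <- match.arg(drug)
  pk <- pk_peak(traj, drug)
  if (pk[["cmax"]] <= 0) {
    warning("half-life undefined for an identically zero curve")
    return(NA_real_)
  }
  col <- if (drug == "x") "x_cen" else "y_cen"
  half <- pk[["cmax"]] / 2
  after <- traj$time > pk[["tmax"]]
  below <- after & traj[[col]] < half
  if (!any(below)) {
    warning("central amount never falls to Cmax/2 within the window; ",
            "half-life undefined")
    return(NA_real_)
  }
  i <- which(below)[1L]
  f <- .central_fun(traj, drug)
  lo <- max(pk[["tmax"]], traj$time[i - 1L])
  stats::uniroot(function(t) f(t) - half, c(lo, traj$time[i]),
                 tol = 1e-10)$root
}

#' Summary PK metrics of a simulated central-compartment curve
#'
#' Computes Cmax, Tmax, AUC over a stated window and the operational
#' half-life (time from dosing to the post-peak crossing of Cmax/2) for
#' one drug.
#'
#' @inheritParams pk_auc
#' @return A one-row data frame with columns `cmax`, `tmax`, `auc`,
#'   `thalf`, `auc_window`.
#' @examples
#' traj <- pk_simulate(make_scenario(), horizon = 40, step = 0.01)
#' pk_metrics(traj, "x")
#' @export
pk_metrics <- function(traj, drug = c("x", "y"), window = c(0, 40)) {
  drug <- match.arg(drug)
  pk <- pk_peak(traj, drug)
  data.frame(cmax = pk[["cmax"]], tmax = pk[["tmax"]],
             auc = pk_auc(traj, drug, window),
             thalf = pk_half_life(traj, drug),
             auc_window = window[2])
}

#' Sweep one interaction coefficient and tabulate PK metrics
#'
#' Re-simulates the system for each value of a chosen interaction
#' coefficient and reports the PK metrics of the affected drug, in the
#' style of a sensitivity table.  Values below the feasibility bound
#' (the effective rate would go negative over the observable range; see
#' [build_constraints()]) are flagged in the `feasible` column and
#' their metrics set to `NA` rather than dropped.
#'
#' @param system baseline [coupled_system()].
#' @param param which coefficient to sweep: one of `"x.g_abs"`,
#'   `"x.g_cp"`, `"x.g_pc"`, `"x.g_el"`, `"y.g_abs"`, `"y.g_cp"`,
#'   `"y.g_pc"`, `"y.g_el"`.
#' @param values numeric vector of coefficient values.
#' @param drug drug whose metrics are reported; defaults to the drug
#'   whose rate the swept coefficient modifies.
#' @param horizon,step,window passed to [pk_simulate()]/[pk_metrics()].
#' @return Data frame with columns `sweep_value`, `feasible`, `cmax`,
#'   `tmax`, `auc`, `thalf`.
#' @examples
#' metrics_table(make_scenario(), "x.g_abs", c(0, 0.4),
#'               horizon = 40, step = 0.01)
#' @export
metrics_table <- function(system, param, values, drug = NULL,
                          horizon = 40, step = 0.001, window = c(0, 40)) {
  stopifnot(param %in% .W_NAMES)
  if (is.null(drug)) drug <- substr(param, 1L, 1L)
  idx <- match(param, .W_NAMES)
  bounds <- .feasibility_bounds(system, horizon = horizon)
  rows <- lapply(values, function(v) {
    if (v < bounds[idx]) {
      return(data.frame(sweep_value = v, feasible = FALSE,
                        cmax = NA_real_, tmax = NA_real_,
                        auc = NA_real_, thalf = NA_real_))
    }
    W <- .system_W(system)
    W[idx] <- v
    traj <- pk_simulate(.set_W(system, W), horizon = horizon, step = step)
    m <- pk_metrics(traj, drug, window)
    data.frame(sweep_value = v, feasible = TRUE, cmax = m$cmax,
               tmax = m$tmax, auc = m$auc, thalf = m$thalf)
  })
  do.call(rbind, rows)
}

# Simulation-side feasibility bounds for the 8 interaction
# coefficients: lower bound -rate / (max driving amount), with the
# driving maxima taken from the uncoupled simulation of the partner
# drug (gut and peripheral drivers bounded by the partner's dose,
# central drivers by its simulated central peak).
.feasibility_bounds <- function(system, horizon = 40) {
  un <- system
  un$drug_x$interactions[] <- 0
  un$drug_y$interactions[] <- 0
  traj <- pk_simulate(un, horizon = horizon, step = 0.01)
  max_x1 <- max(traj$x_cen); max_y1 <- max(traj$y_cen)
  rx <- system$drug_x$rates; ry <- system$drug_y$rates
  dx <- system$drug_x$dose;  dy <- system$drug_y$dose
  b <- c(-rx[["k_abs"]] / dy,     -rx[["k_cp"]] / max_y1,
         -rx[["k_pc"]] / dy,      -rx[["k_el"]] / max_y1,
         -ry[["k_abs"]] / dx,     -ry[["k_cp"]] / max_x1,
         -ry[["k_pc"]] / dx,      -ry[["k_el"]] / max_x1)
  names(b) <- .W_NAMES
  b
}
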