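#' Observed central-amount series for the interaction fit
#'
#' Packages the observed central-compartment amount series of both
#' drugs, each on its own sampling grid, together with the amount scale
#' the series are expressed on.  The stage-2 objective compares model
#' central amounts with these series on the stated scale.
#'
#' The package's canonical amount unit is 10^3 mg, but the default
#' fitting scale is mg (`scale = "mg"`): on that scale the residual sum
#' of squares is large relative to the L2 penalty, so the
#' regularization strength `lambda` acts as the mild stabilizer the
#' estimation procedure intends (see the methods vignette for the
#' scaling analysis).
#'
#' @param times_x,times_y sampling times (h) for drug X and drug Y.
#' @param obs_x,obs_y observed central amounts at those times, on
#'   `scale`.
#' @param scale `"mg"` or `"10^3mg"`.
#' @return An object of class `pk_observations`.
#' @export
pk_observations <- function(times_x, obs_x, times_y, obs_y,
                            scale = c("mg", "10^3mg")) {
  scale <- match.arg(scale)
  stopifnot(length(times_x) == length(obs_x),
            length(times_y) == length(obs_y),
            length(obs_x) >= 1L, length(obs_y) >= 1L,
            all(times_x >= 0), all(times_y >= 0))
  structure(list(times_x = as.numeric(times_x),
                 obs_x = as.numeric(obs_x),
                 times_y = as.numeric(times_y),
                 obs_y = as.numeric(obs_y), scale = scale),
            class = "pk_observations")
}

# Convert a replicate data frame from add_noise() (amounts in 10^3 mg)
# to a pk_observations object on the fitting scale.
.obs_from_replicate <- function(rep_df, scale = "mg") {
  f <- if (scale == "mg") 1000 else 1
  pk_observations(rep_df$time, rep_df$x_obs * f,
                  rep_df$time, rep_df$y_obs * f, scale = scale)
}

#' Practical bounds for the eight interaction coefficients
#'
#' Each interaction coefficient must keep its effective rate
#' non-negative, which bounds it below by `-rate / (max driving
#' amount)`.  The unobservable driving amounts are replaced by
#' experimentally determinable surrogates: the partner's initial dose
#' for the gut and peripheral drivers, and the maximum *observed*
#' central amount for the central drivers.  The zero vector is always
#' feasible.  Upper bounds, which the rate constraints do not supply,
#' are set symmetrically as `upper_factor` times the magnitude of the
#' lower bound.
#'
#' @param system a [coupled_system()] carrying the stage-1 rates and
#'   doses.
#' @param obs_x,obs_y observed central-amount series (10^3 mg) for
#'   drug X and Y; required for the central-driver bounds.
#' @param upper_factor multiple of `|lower|` used as the upper bound
#'   (default 10).
#' @return An object of class `pk_constraints`: list with `lower`,
#'   `upper` (named 8-vectors ordered as `x.g_abs`, `x.g_cp`,
#'   `x.g_pc`, `x.g_el`, `y.g_abs`, `y.g_cp`, `y.g_pc`, `y.g_el`),
#'   `scale` (the diagonal of the driving-amount matrix) and `baseline`
#'   (the rate vector).
#' @examples
#' sys <- make_scenario()
#' traj <- pk_simulate(sys, horizon = 12, step = 0.01)
#' build_constraints(sys, obs_x = traj$x_cen, obs_y = traj$y_cen)
#' @export
build_constraints <- function(system, obs_x, obs_y, upper_factor = 10) {
  stopifnot(inherits(system, "coupled_system"))
  if (missing(obs_x) || length(obs_x) == 0L || all(!is.finite(obs_x)))
    stop("observed drug-X central series is required for the ",
         "y.g_cp and y.g_el bounds", call. = FALSE)
  if (missing(obs_y) || length(obs_y) == 0L || all(!is.finite(obs_y)))
    stop("observed drug-Y central series is required for the ",
         "x.g_cp and x.g_el bounds", call. = FALSE)
  rx <- system$drug_x$rates; ry <- system$drug_y$rates
  dx <- system$drug_x$dose;  dy <- system$drug_y$dose
  max_x1 <- max(obs_x); max_y1 <- max(obs_y)
  if (dx <= 0 || dy <= 0 || max_x1 <= 0 || max_y1 <= 0)
    stop("doses and observed central maxima must be positive to form ",
         "the bounds", call. = FALSE)
  scale <- c(dy, max_y1, dy, max_y1, dx, max_x1, dx, max_x1)
  baseline <- c(rx[["k_abs"]], rx[["k_cp"]], rx[["k_pc"]], rx[["k_el"]],
                ry[["k_abs"]], ry[["k_cp"]], ry[["k_pc"]], ry[["k_el"]])
  lower <- -baseline / scale
  upper <- upper_factor * abs(lower)
  names(lower) <- names(upper) <- names(scale) <- names(baseline) <- .W_NAMES
  structure(list(lower = lower, upper = upper, scale = scale,
                 baseline = baseline, upper_factor = upper_factor),
            class = "pk_constraints")
}

#' @export
print.pk_constraints <- function(x, ...) {
  cat("Interaction-coefficient box constraints (10^3/(mg h))\n")
  print(data.frame(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Regularized least-squares objective of the stage-2 fit
#'
#' Evaluates `z = SSEx + SSEy + lambda * L2` for a candidate
#' interaction vector `W`: the coupled system (with stage-1 rates from
#' `system` and interactions `W`) is simulated at the observation
#' times, `SSEx` and `SSEy` are the mean squared deviations of the two
#' central-amount series on the observations' scale, and
#' `L2 = sum(W^2)` (a plain sum of squares, no square root).
#'
#' A candidate at which the integration fails (e.g. an effective rate
#' driven far negative) receives a large penalty value rather than an
#' error, so a global optimizer can move past it.
#'
#' @param W numeric 8-vector of interaction coefficients, ordered as
#'   `x.g_abs`, `x.g_cp`, `x.g_pc`, `x.g_el`, `y.g_abs`, `y.g_cp`,
#'   `y.g_pc`, `y.g_el`.
#' @param system a [coupled_system()] carrying doses and stage-1 rates
#'   (its own interaction entries are ignored).
#' @param obs a [pk_observations()].
#' @param lambda regularization strength, >= 0.
#' @param rtol,atol integration tolerances for the model evaluation.
#' @return The objective value `z` (invisibly carries components as
#'   attribute `"components"`).
#' @export
objective_value <- function(W, system, obs, lambda = 0,
                            rtol = 1e-7, atol = 1e-10) {
  stopifnot(inherits(obs, "pk_observations"), lambda >= 0,
            length(W) == 8L)
  # infeasible candidates can stall the solver; silence its console
  # diagnostics and convert failures into a penalty value
  sim <- tryCatch({
    res <- NULL
    utils::capture.output(suppressWarnings(
      res <- .central_both(.set_W(system, W), obs$times_x, obs$times_y,
                           rtol = rtol, atol = atol)))
    res
  }, error = function(e) NULL)
  if (is.null(sim)) {
    z <- 1e12
    attr(z, "components") <- c(sse_x = NA_real_, sse_y = NA_real_,
                               l2 = sum(W^2))
    return(z)
  }
  f <- if (obs$scale == "mg") 1000 else 1
  sse_x <- mean((sim$x * f - obs$obs_x)^2)
  sse_y <- mean((sim$y * f - obs$obs_y)^2)
  l2 <- sum(W^2)
  z <- sse_x + sse_y + lambda * l2
  attr(z, "components") <- c(sse_x = sse_x, sse_y = sse_y, l2 = l2)
  z
}
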