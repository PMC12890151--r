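#' Built-in simulation scenarios
#'
#' `make_scenario()` builds a ready-made [coupled_system()]:
#'
#' * `"table1"` — the benchmark pair used throughout the package's
#'   simulation studies: doses 0.6 and 1 (10^3 mg); drug X rates all
#'   0.5 h^-1; drug Y rates 0.6, 0.5, 0.4, 0.3 h^-1; all interaction
#'   coefficients zero unless overridden.
#' * `"metcap_synthetic"` — a synthetic metoprolol (X) / captopril (Y)
#'   stand-in parameterized from published fitted values (50 mg doses,
#'   Vc 4163.137 ml for both drugs, all eight interaction coefficients
#'   active).  It is used to exercise the end-to-end pipeline; it is
#'   generated data, not the underlying clinical measurements.
#'
#' Interaction overrides are passed by name (e.g. `x.g_abs = 0.4`); a
#' value below its feasibility bound (the effective rate would go
#' negative over the observable range) is rejected with the violated
#' bound named.
#'
#' @param name scenario name.
#' @param ... interaction overrides named among `x.g_abs`, `x.g_cp`,
#'   `x.g_pc`, `x.g_el`, `y.g_abs`, `y.g_cp`, `y.g_pc`, `y.g_el`.
#' @return A [coupled_system()].
#' @examples
#' make_scenario()
#' make_scenario("table1", x.g_abs = 0.4)
#' @export
make_scenario <- function(name = c("table1", "metcap_synthetic"), ...) {
  name <- match.arg(name)
  sys <- switch(name,
    table1 = coupled_system(
      drug_spec(dose = 0.6, k_abs = 0.5, k_cp = 0.5, k_pc = 0.5,
                k_el = 0.5),
      drug_spec(dose = 1.0, k_abs = 0.6, k_cp = 0.5, k_pc = 0.4,
                k_el = 0.3)),
    metcap_synthetic = coupled_system(
      drug_spec(dose = 0.05, k_abs = 0.205, k_cp = 84.192, k_pc = 8.122,
                k_el = 15.162,
                g_abs = -1.270, g_cp = -729.2, g_pc = 585.2, g_el = -4854,
                v_central = 4163.137),
      drug_spec(dose = 0.05, k_abs = 0.716, k_cp = 69.474, k_pc = 19.222,
                k_el = 14.591,
                g_abs = -2.354, g_cp = -9704, g_pc = 4905, g_el = -2481,
                v_central = 4163.137)))
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .W_NAMES)
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown interaction override(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    bounds <- .feasibility_bounds(sys)
    W <- .system_W(sys)
    for (nm in names(over)) {
      v <- over[[nm]]
      if (v < bounds[[nm]])
        stop(sprintf(
          "override %s = %g violates the feasibility bound %s > %.6g",
          nm, v, nm, bounds[[nm]]), call. = FALSE)
      W[[nm]] <- v
    }
    sys <- .set_W(sys, W)
  }
  sys
}

#' Measurement-noise specification for synthetic datasets
#'
#' Describes the observation model used by [add_noise()] and
#' [make_dataset()]: at each sampling time the observed central amount
#' is the true amount plus zero-mean Gaussian noise, truncated at zero.
#' Under the default proportional model the noise standard deviation is
#' `sd_frac` times the amount at that time; under the additive model it
#' is `sd_frac` in absolute amount units.
#'
#' @param sd_frac noise scale (default 0.1).
#' @param n_reps number of replicate observation sets (default 100).
#' @param seed RNG seed; mandatory for reproducibility.
#' @param times sampling times, h.  The default grid 0.25-12 h (13
#'   points) mirrors a typical single-dose clinical sampling design.
#' @param model `"proportional"` (default) or `"additive"`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_frac = 0.1, n_reps = 100, seed,
                       times = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5,
                                 3, 4, 6, 8, 12),
                       model = c("proportional", "additive")) {
  model <- match.arg(model)
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is required for reproducible noise generation",
         call. = FALSE)
  if (sd_frac < 0) stop("'sd_frac' must be non-negative", call. = FALSE)
  if (n_reps < 1) stop("'n_reps' must be at least 1", call. = FALSE)
  structure(list(sd_frac = sd_frac, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), times = sort(times),
                 model = model),
            class = "noise_spec")
}

# Evaluate both central curves at the sampling times by spline
# interpolation of a trajectory.
.sample_centrals <- function(traj, times) {
  if (max(times) > max(traj$time) + 1e-9)
    stop("sampling times exceed the trajectory span", call. = FALSE)
  list(x = .central_fun(traj, "x")(times),
       y = .central_fun(traj, "y")(times))
}

#' Generate noisy replicate observation sets from a trajectory
#'
#' Samples both drugs' central-compartment amounts at the noise spec's
#' sampling times and produces `n_reps` independent noisy replicates
#' under the spec's observation model (see [noise_spec()]).  Negative
#' draws are truncated at zero.  Generation is seeded and leaves the
#' global RNG state untouched.
#'
#' @param traj a `pk_trajectory` covering the sampling times.
#' @param noise a [noise_spec()].
#' @return A list of `n_reps` data frames with columns `time`, `x_obs`,
#'   `y_obs` (amounts, 10^3 mg).
#' @examples
#' traj <- pk_simulate(make_scenario(), horizon = 12, step = 0.01)
#' reps <- add_noise(traj, noise_spec(n_reps = 3, seed = 1))
#' @export
add_noise <- function(traj, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  cen <- .sample_centrals(traj, noise$times)
  n <- length(noise$times)
  .with_preserved_rng(noise$seed, {
    lapply(seq_len(noise$n_reps), function(r) {
      sd_x <- if (noise$model == "proportional")
        noise$sd_frac * cen$x else rep(noise$sd_frac, n)
      sd_y <- if (noise$model == "proportional")
        noise$sd_frac * cen$y else rep(noise$sd_frac, n)
      data.frame(
        time = noise$times,
        x_obs = pmax(0, cen$x + stats::rnorm(n, 0, sd_x)),
        y_obs = pmax(0, cen$y + stats::rnorm(n, 0, sd_y)))
    })
  })
}

# Run `expr` with a local RNG seed, restoring the caller's RNG state.
.with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a long-format observation dataset from a scenario
#'
#' Simulates the requested regimen (for a single-drug regimen the
#' partner's dose is set to zero, which uncouples the system) and emits
#' the package's long observation schema, one block of rows per
#' replicate and drug.  Concentrations are amounts divided by the
#' drug's `v_central` when present (unit `"10^3mg/ml"`), otherwise the
#' amounts themselves with an implied unit volume.
#'
#' @param system a [coupled_system()].
#' @param regimen `"combined"`, `"single-x"` or `"single-y"`.
#' @param noise a [noise_spec()].
#' @param horizon,step passed to [pk_simulate()]; the horizon defaults
#'   to just past the last sampling time.
#' @return A data frame with columns `subject_id`, `drug`, `regimen`,
#'   `time_h`, `concentration`, `conc_unit`, `dose_mg`.
#' @examples
#' ds <- make_dataset(make_scenario(), "combined",
#'                    noise_spec(n_reps = 2, seed = 7))
#' head(ds)
#' @export
make_dataset <- function(system, regimen = c("combined", "single-x",
                                             "single-y"),
                         noise, horizon = NULL, step = 0.005) {
  regimen <- match.arg(regimen)
  stopifnot(inherits(system, "coupled_system"),
            inherits(noise, "noise_spec"))
  if (is.null(horizon)) horizon <- max(noise$times) * 1.05
  sim_sys <- system
  if (regimen == "single-x") sim_sys$drug_y$dose <- 0
  if (regimen == "single-y") sim_sys$drug_x$dose <- 0
  traj <- pk_simulate(sim_sys, horizon = horizon, step = step)
  reps <- add_noise(traj, noise)
  regimen_label <- if (regimen == "combined") "combined" else "single"
  drugs <- switch(regimen, combined = c("x", "y"),
                  `single-x` = "x", `single-y` = "y")
  rows <- lapply(seq_along(reps), function(r) {
    do.call(rbind, lapply(drugs, function(d) {
      spec <- if (d == "x") system$drug_x else system$drug_y
      amt <- if (d == "x") reps[[r]]$x_obs else reps[[r]]$y_obs
      vc <- if (is.null(spec$v_central)) 1 else spec$v_central
      data.frame(subject_id = r, drug = toupper(d),
                 regimen = regimen_label, time_h = reps[[r]]$time,
                 concentration = amt / vc, conc_unit = "10^3mg/ml",
                 dose_mg = spec$dose * 1000)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
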