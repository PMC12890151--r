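#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with the total sum of squares taken
#' about the observed mean.
#'
#' @param observed,fitted numeric vectors of equal length (>= 2).
#' @return Dimensionless R-squared (<= 1; can be negative for fits
#'   worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2L)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot <= 0)
    stop("observed series has zero variance; R^2 undefined", call. = FALSE)
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Least-squares Akaike information criterion
#'
#' Gaussian least-squares form `AIC = n * log(SSE / n) + 2k`, the usual
#' criterion when only a residual sum of squares (not a likelihood) is
#' available.
#'
#' @param sse residual sum of squares (> 0).
#' @param n number of observations (> 0).
#' @param k number of free parameters.
#' @return AIC value.
#' @export
aic_ls <- function(sse, n, k) {
  stopifnot(n > 0, sse > 0, k >= 0)
  n * log(sse / n) + 2 * k
}

# ---------------------------------------------------------------------
# Stage 1: monotherapy fit of the four rates (and optionally Vc)
# ---------------------------------------------------------------------

#' Fit the uncoupled model to one drug's monotherapy curve
#'
#' Nonlinear least squares of the closed-form uncoupled solution
#' ([analytic_uncoupled()]) to a single-drug concentration- or
#' amount-time series, with multi-start Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) on log-parameters to enforce positivity.
#' When `values` are concentrations the apparent central volume is
#' estimated alongside the four rates; when they are amounts (or
#' `v_central` is supplied) only the rates are free.
#'
#' The tri-exponential curve is subject to the classic "flip-flop"
#' ambiguity (exchanging the role of the absorption exponent can fit
#' equally well).  Among starts whose residual sum of squares ties the
#' best within a factor of 1+1e-6, the fit with the smallest
#' absorption rate is returned, i.e. absorption-rate-limited kinetics
#' are preferred; see the methods vignette.
#'
#' @param times sampling times, h; at least 6 distinct values.
#' @param values observed series: central amounts (10^3 mg) if `type =
#'   "amount"`, plasma concentrations otherwise.
#' @param dose administered dose, 10^3 mg.
#' @param type `"amount"` or `"concentration"`.
#' @param v_central known apparent central volume (ml); if `NULL` and
#'   `type = "concentration"` it is estimated.
#' @param unit concentration unit (see [amount_from_concentration()]).
#' @param n_starts number of multi-start initializations.
#' @param seed RNG seed for the randomized starts.
#' @return An object of class `pk_monofit`: list with `rates`,
#'   `v_central`, `fitted`, `residuals`, `sse`, `r2`, `n_starts_used`.
#' @examples
#' tt <- seq(0.25, 12, length.out = 25)
#' amt <- analytic_uncoupled(
#'   c(k_abs = 0.5, k_cp = 0.5, k_pc = 0.5, k_el = 0.5), 0.6, tt)
#' fit <- fit_monotherapy(tt, amt, dose = 0.6, type = "amount")
#' fit$rates
#' @export
fit_monotherapy <- function(times, values, dose,
                            type = c("concentration", "amount"),
                            v_central = NULL, unit = "10^3mg/ml",
                            n_starts = 24, seed = 1) {
  type <- match.arg(type)
  stopifnot(length(times) == length(values), all(values >= 0), dose > 0)
  if (length(unique(times)) < 6L)
    stop("at least 6 distinct sampling times are required (5 free ",
         "quantities)", call. = FALSE)
  ord <- order(times)
  times <- times[ord]; values <- values[ord]

  estimate_v <- (type == "concentration") && is.null(v_central)
  if (type == "amount") {
    amounts <- values
    vc_fixed <- if (is.null(v_central)) 1 else v_central
  } else if (!is.null(v_central)) {
    amounts <- amount_from_concentration(values, v_central, unit)
    vc_fixed <- v_central
  } else {
    # fit in concentration space; Vc is the 5th parameter
    values <- values * .conc_unit_factor(unit)  # to (10^3 mg)/ml
    amounts <- NULL
    vc_fixed <- NA_real_
  }

  resid_fun <- function(logp) {
    rates <- c(k_abs = exp(logp[1]), k_cp = exp(logp[2]),
               k_pc = exp(logp[3]), k_el = exp(logp[4]))
    if (any(!is.finite(rates)) || any(rates > 1e4))
      return(rep(1e6, length(times)))
    mod <- analytic_uncoupled(rates, dose, times)
    if (estimate_v) mod / exp(logp[5]) - values
    else mod - amounts
  }

  # heuristic center for the starts: terminal slope for k_el, inverse
  # of the observed peak time for k_abs
  i_pk <- which.max(values)
  t_pk <- max(times[i_pk], min(times))
  tail_i <- times > t_pk & values > 0
  kel0 <- if (sum(tail_i) >= 2) {
    sl <- stats::coef(stats::lm(log(values[tail_i]) ~ times[tail_i]))[2]
    max(0.05, min(10, -sl))
  } else 0.5
  ka0 <- max(0.1, min(10, 1.6 / t_pk))
  v0 <- if (estimate_v) max(values[i_pk], 1e-12) else NA
  v0 <- if (estimate_v) dose / v0 / 4 else NA  # rough Vc from Cmax

  base <- log(c(ka0, kel0, kel0, kel0))
  starts <- .with_preserved_rng(seed, {
    lapply(seq_len(n_starts), function(i) {
      jit <- if (i == 1L) rep(0, 4L) else stats::rnorm(4L, 0, 1.2)
      p <- base + jit
      if (estimate_v)
        c(p, log(v0) + if (i == 1L) 0 else stats::rnorm(1L, 0, 1))
      else p
    })
  })

  fits <- lapply(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200L, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("monotherapy fit failed to converge from any start", call. = FALSE)
  sses <- vapply(fits, function(f) sum(f$fvec^2), numeric(1L))
  best_sse <- min(sses)
  near <- which(sses <= best_sse * (1 + 1e-6) + 1e-300)
  kas <- vapply(fits[near], function(f) exp(f$par[1]), numeric(1L))
  best <- fits[[near[which.min(kas)]]]

  logp <- best$par
  rates <- c(k_abs = exp(logp[1]), k_cp = exp(logp[2]),
             k_pc = exp(logp[3]), k_el = exp(logp[4]))
  vc <- if (estimate_v) exp(logp[5]) else vc_fixed
  fitted_vals <- if (estimate_v)
    analytic_uncoupled(rates, dose, times) / vc
  else analytic_uncoupled(rates, dose, times)
  obs_for_r2 <- if (estimate_v) values else amounts
  structure(list(rates = rates, v_central = vc, dose = dose,
                 times = times, observed = obs_for_r2,
                 fitted = as.numeric(fitted_vals),
                 residuals = as.numeric(obs_for_r2 - fitted_vals),
                 sse = sum((obs_for_r2 - fitted_vals)^2),
                 r2 = r_squared(obs_for_r2, as.numeric(fitted_vals)),
                 n_starts_used = length(fits)),
            class = "pk_monofit")
}

#' @export
print.pk_monofit <- function(x, ...) {
  cat("Monotherapy two-compartment fit\n")
  cat("  rates (h^-1):",
      paste(names(x$rates), signif(x$rates, 5), sep = "=",
            collapse = "  "), "\n")
  cat("  Vc (ml):", signif(x$v_central, 7),
      " SSE:", format(x$sse, digits = 4),
      " R^2:", round(x$r2, 4), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------
# Stage 2: constrained, regularized PSO fit of the interaction vector
# ---------------------------------------------------------------------

#' Fit the eight interaction coefficients by constrained PSO
#'
#' Stage 2 of the hierarchical estimator: with the monotherapy rates
#' and doses fixed in `system`, the interaction vector W is estimated
#' by globally minimizing [objective_value()] over the box given by
#' [build_constraints()] using seeded particle swarm optimization
#' ([pso_optim()]).  Entries named in `fix_zero` are pinned to zero and
#' excluded from the search (used by [ablation_study()]).
#'
#' @param obs a [pk_observations()].
#' @param system a [coupled_system()] with stage-1 rates and doses.
#' @param lambda regularization strength (default 0.6).
#' @param constraints a [build_constraints()] result; built from `obs`
#'   if omitted.
#' @param control a [pso_control()]; the seed is mandatory.
#' @param fix_zero character vector of interaction names pinned to 0.
#' @return An object of class `pk_interfit`: `W` (named 8-vector), the
#'   objective value `z` and its components, per-drug `r2`, `aic`,
#'   the bounds actually searched, and the optimizer log.
#' @examples
#' \donttest{
#' sys <- make_scenario(x.g_abs = 0.4)
#' traj <- pk_simulate(sys, horizon = 13, step = 0.01)
#' d <- add_noise(traj, noise_spec(sd_frac = 0, n_reps = 1, seed = 1))[[1]]
#' obs <- pk_observations(d$time, d$x_obs * 1000, d$time, d$y_obs * 1000)
#' fit <- fit_interactions(obs, make_scenario(), lambda = 0,
#'                         control = pso_control(seed = 1))
#' fit$W
#' }
#' @export
fit_interactions <- function(obs, system, lambda = 0.6,
                             constraints = NULL, control,
                             fix_zero = character()) {
  stopifnot(inherits(obs, "pk_observations"),
            inherits(system, "coupled_system"),
            inherits(control, "pso_control"))
  if (is.null(constraints)) {
    f <- if (obs$scale == "mg") 1e-3 else 1
    constraints <- build_constraints(system, obs_x = obs$obs_x * f,
                                     obs_y = obs$obs_y * f)
  }
  stopifnot(inherits(constraints, "pk_constraints"))
  if (length(fix_zero) && !all(fix_zero %in% .W_NAMES))
    stop("'fix_zero' must name interaction coefficients among: ",
         paste(.W_NAMES, collapse = ", "), call. = FALSE)
  free <- !(.W_NAMES %in% fix_zero)
  W <- setNames(numeric(8L), .W_NAMES)

  fn <- function(p) {
    W[free] <- p
    as.numeric(objective_value(W, system, obs, lambda = lambda))
  }
  opt <- pso_optim(fn, constraints$lower[free], constraints$upper[free],
                   control)
  W[free] <- opt$par

  z <- objective_value(W, system, obs, lambda = lambda,
                       rtol = 1e-9, atol = 1e-12)
  comp <- attr(z, "components")
  sim <- .central_both(.set_W(system, W), obs$times_x, obs$times_y,
                       rtol = 1e-9, atol = 1e-12)
  fscale <- if (obs$scale == "mg") 1000 else 1
  fit_x <- sim$x * fscale; fit_y <- sim$y * fscale
  n_tot <- length(obs$obs_x) + length(obs$obs_y)
  sse_sum <- sum((fit_x - obs$obs_x)^2) + sum((fit_y - obs$obs_y)^2)
  structure(list(
    W = W, z = as.numeric(z),
    sse_x = comp[["sse_x"]], sse_y = comp[["sse_y"]], l2 = comp[["l2"]],
    r2_x = r_squared(obs$obs_x, fit_x),
    r2_y = r_squared(obs$obs_y, fit_y),
    aic = aic_ls(sse_sum, n_tot, sum(free)),
    lambda = lambda, constraints = constraints, fix_zero = fix_zero,
    fitted_x = fit_x, fitted_y = fit_y, obs = obs,
    optimizer = opt[c("iterations", "evaluations", "value")],
    control = control),
    class = "pk_interfit")
}

#' @export
print.pk_interfit <- function(x, ...) {
  cat("Stage-2 interaction fit (lambda =", x$lambda, ")\n")
  print(signif(x$W, 5))
  cat(sprintf("z = %.6g  R^2(X) = %.4f  R^2(Y) = %.4f  AIC = %.2f\n",
              x$z, x$r2_x, x$r2_y, x$aic))
  invisible(x)
}

# ---------------------------------------------------------------------
# Full two-stage fit on a long observation table
# ---------------------------------------------------------------------

#' Hierarchical two-stage fit of the coupled model
#'
#' The main fitting interface.  Stage 1 fits each drug's four rate
#' constants and apparent central volume to its single-administration
#' rows, per subject, by [fit_monotherapy()]; the across-subject means
#' define the uncoupled backbone.  Stage 2 fixes those rates and fits
#' the eight interaction coefficients to each subject's
#' combined-administration rows by constrained, L2-regularized PSO
#' ([fit_interactions()]); coefficients are summarized across subjects
#' by their mean and normal-theory 95% CI.
#'
#' @param data a long observation table with columns `subject_id`,
#'   `drug`, `regimen` (`"single"`/`"combined"`), `time_h`,
#'   `concentration`, `conc_unit`, `dose_mg` — as returned by
#'   [read_observations()] or [make_dataset()].
#' @param drug_x,drug_y labels in `data$drug` naming which drug plays X
#'   and Y; default: first two labels in order of appearance.
#' @param lambda regularization strength for stage 2.
#' @param control a [pso_control()]; each subject's stage-2 seed is
#'   derived from its seed.
#' @param upper_factor upper-bound multiple for [build_constraints()].
#' @param stage1 optional list of per-drug stage-1 results or known
#'   rates to use instead of fitting stage 1 (elements `x` and `y`,
#'   each a `pk_monofit` or a list with `rates`, `v_central`).
#' @return An object of class `coupledpk_fit` with `print()`,
#'   `summary()`, `coef()`, `predict()`, `plot()`, `residuals()` and
#'   `simulate()` methods.
#' @export
fit_coupled <- function(data, drug_x = NULL, drug_y = NULL,
                        lambda = 0.6, control, upper_factor = 10,
                        stage1 = NULL) {
  data <- .validate_obs_table(data)
  stopifnot(inherits(control, "pso_control"))
  labels <- unique(data$drug)
  if (is.null(drug_x)) drug_x <- labels[1L]
  if (is.null(drug_y)) drug_y <- labels[2L]
  if (is.na(drug_y))
    stop("two drugs are required; found only '", drug_x, "'",
         call. = FALSE)

  one_stage1 <- function(label, idx) {
    if (!is.null(stage1) && !is.null(stage1[[idx]])) {
      s <- stage1[[idx]]
      return(list(rates = s$rates, v_central = s$v_central,
                  per_subject = NULL, r2 = s$r2 %||% NA_real_))
    }
    rows <- data[data$drug == label & data$regimen == "single", ]
    if (!nrow(rows))
      stop("no single-administration rows for '", label,
           "'; supply 'stage1' instead", call. = FALSE)
    subs <- split(rows, rows$subject_id)
    fits <- lapply(subs, function(s) {
      fit_monotherapy(s$time_h, s$conc, dose = s$dose[1L],
                      type = "concentration", seed = control$seed)
    })
    rates_mat <- t(vapply(fits, `[[`, numeric(4L), "rates"))
    vcs <- vapply(fits, `[[`, numeric(1L), "v_central")
    list(rates = colMeans(rates_mat), v_central = mean(vcs),
         per_subject = fits,
         r2 = mean(vapply(fits, `[[`, numeric(1L), "r2")))
  }
  s1x <- one_stage1(drug_x, "x")
  s1y <- one_stage1(drug_y, "y")

  comb <- data[data$regimen == "combined", ]
  if (!nrow(comb))
    stop("no combined-administration rows; stage 2 needs them",
         call. = FALSE)
  subjects <- unique(comb$subject_id)

  # A subject's stage-2 fit is anchored to that subject's own stage-1
  # parameters when available (the monotherapy problem can have
  # equal-SSE parameter ridges, so averaging rate constants across
  # subjects does not generally reproduce any subject's curve); the
  # across-subject means are reported as the stage-1 summary.
  subject_stage1 <- function(s1, sid) {
    if (!is.null(s1$per_subject) &&
        !is.null(s1$per_subject[[as.character(sid)]]))
      s1$per_subject[[as.character(sid)]]
    else s1
  }
  subject_fit <- function(sid, i) {
    sc <- comb[comb$subject_id == sid, ]
    rx <- sc[sc$drug == drug_x, ]; ry <- sc[sc$drug == drug_y, ]
    if (!nrow(rx) || !nrow(ry))
      stop("subject ", sid, " lacks combined rows for both drugs",
           call. = FALSE)
    px <- subject_stage1(s1x, sid); py <- subject_stage1(s1y, sid)
    sys <- coupled_system(
      drug_spec(dose = rx$dose[1L],
                k_abs = px$rates[["k_abs"]], k_cp = px$rates[["k_cp"]],
                k_pc = px$rates[["k_pc"]], k_el = px$rates[["k_el"]],
                v_central = px$v_central),
      drug_spec(dose = ry$dose[1L],
                k_abs = py$rates[["k_abs"]], k_cp = py$rates[["k_cp"]],
                k_pc = py$rates[["k_pc"]], k_el = py$rates[["k_el"]],
                v_central = py$v_central))
    amt_x <- rx$conc * px$v_central   # 10^3 mg
    amt_y <- ry$conc * py$v_central
    obs <- pk_observations(rx$time_h, amt_x * 1000,
                           ry$time_h, amt_y * 1000, scale = "mg")
    cons <- build_constraints(sys, obs_x = amt_x, obs_y = amt_y,
                              upper_factor = upper_factor)
    ctl <- control
    ctl$seed <- (control$seed + 7919L * i) %% .Machine$integer.max
    fit_interactions(obs, sys, lambda = lambda, constraints = cons,
                     control = ctl)
  }
  s2 <- Map(subject_fit, subjects, seq_along(subjects))

  Wmat <- t(vapply(s2, `[[`, numeric(8L), "W"))
  W_mean <- colMeans(Wmat)
  W_se <- apply(Wmat, 2L, stats::sd) / sqrt(nrow(Wmat))
  ci <- cbind(lower = W_mean - 1.96 * W_se, upper = W_mean + 1.96 * W_se)

  pooled_r2 <- function(which_drug) {
    obs <- unlist(lapply(s2, function(f)
      if (which_drug == "x") f$obs$obs_x else f$obs$obs_y))
    fit <- unlist(lapply(s2, function(f)
      if (which_drug == "x") f$fitted_x else f$fitted_y))
    r_squared(obs, fit)
  }
  n_tot <- sum(vapply(s2, function(f)
    length(f$obs$obs_x) + length(f$obs$obs_y), numeric(1L)))
  sse_tot <- sum(vapply(s2, function(f)
    sum((f$fitted_x - f$obs$obs_x)^2) + sum((f$fitted_y - f$obs$obs_y)^2),
    numeric(1L)))

  structure(list(
    drug_labels = c(x = drug_x, y = drug_y),
    stage1 = list(x = s1x, y = s1y),
    stage2 = s2, W = W_mean, W_ci = ci, W_by_subject = Wmat,
    r2 = c(x = pooled_r2("x"), y = pooled_r2("y")),
    aic = aic_ls(sse_tot, n_tot, 8L),
    lambda = lambda, control = control, n_subjects = length(subjects),
    call = match.call()),
    class = "coupledpk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean-parameter system implied by a coupledpk_fit, with doses from the
# first stage-2 subject fit.
.fit_system <- function(object) {
  f1 <- object$stage2[[1L]]
  s1x <- object$stage1$x; s1y <- object$stage1$y
  dx <- f1$constraints$scale[["y.g_abs"]]
  dy <- f1$constraints$scale[["x.g_abs"]]
  sys <- coupled_system(
    drug_spec(dose = dx, k_abs = s1x$rates[["k_abs"]],
              k_cp = s1x$rates[["k_cp"]], k_pc = s1x$rates[["k_pc"]],
              k_el = s1x$rates[["k_el"]], v_central = s1x$v_central),
    drug_spec(dose = dy, k_abs = s1y$rates[["k_abs"]],
              k_cp = s1y$rates[["k_cp"]], k_pc = s1y$rates[["k_pc"]],
              k_el = s1y$rates[["k_el"]], v_central = s1y$v_central))
  .set_W(sys, object$W)
}

#' @export
print.coupledpk_fit <- function(x, ...) {
  cat("Coupled PK two-stage fit\n")
  cat(sprintf("  drugs: X = %s, Y = %s   subjects: %d   lambda = %g\n",
              x$drug_labels[["x"]], x$drug_labels[["y"]],
              x$n_subjects, x$lambda))
  cat("  interaction coefficients (mean):\n")
  print(signif(x$W, 5))
  cat(sprintf("  R^2: X %.4f, Y %.4f   AIC %.2f\n",
              x$r2[["x"]], x$r2[["y"]], x$aic))
  invisible(x)
}

#' @export
summary.coupledpk_fit <- function(object, ...) {
  cat("Coupled two-compartment PK model, hierarchical two-stage fit\n\n")
  cat("Stage 1 (monotherapy rates, h^-1; Vc, ml):\n")
  for (d in c("x", "y")) {
    s <- object$stage1[[d]]
    cat(sprintf("  %s: %s  Vc=%.4g\n", object$drug_labels[[d]],
                paste(names(s$rates), signif(s$rates, 5), sep = "=",
                      collapse = " "), s$v_central))
  }
  cat("\nStage 2 (interaction coefficients, 10^3/(mg h)):\n")
  tab <- data.frame(estimate = object$W,
                    ci_lower = object$W_ci[, "lower"],
                    ci_upper = object$W_ci[, "upper"])
  print(signif(tab, 5))
  cat(sprintf("\nR^2: X %.4f, Y %.4f    AIC %.2f    subjects %d\n",
              object$r2[["x"]], object$r2[["y"]], object$aic,
              object$n_subjects))
  invisible(object)
}

#' @export
coef.coupledpk_fit <- function(object, ...) {
  s1x <- object$stage1$x; s1y <- object$stage1$y
  c(setNames(s1x$rates, paste0("x.", names(s1x$rates))),
    x.v_central = s1x$v_central,
    setNames(s1y$rates, paste0("y.", names(s1y$rates))),
    y.v_central = s1y$v_central,
    object$W)
}

#' @param object,x a `coupledpk_fit`.
#' @param times prediction times, h.
#' @param type `"amount"` (10^3 mg) or `"concentration"`.
#' @param ... unused.
#' @rdname fit_coupled
#' @export
predict.coupledpk_fit <- function(object, times = seq(0, 12, by = 0.1),
                                  type = c("amount", "concentration"),
                                  ...) {
  type <- match.arg(type)
  sys <- .fit_system(object)
  sim <- .central_both(sys, times, times, rtol = 1e-9, atol = 1e-12)
  out <- data.frame(time_h = times, x = sim$x, y = sim$y)
  if (type == "concentration") {
    out$x <- out$x / sys$drug_x$v_central
    out$y <- out$y / sys$drug_y$v_central
  }
  names(out)[2:3] <- object$drug_labels
  out
}

#' @export
residuals.coupledpk_fit <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$stage2), function(i) {
    f <- object$stage2[[i]]
    rbind(
      data.frame(subject = i, drug = object$drug_labels[["x"]],
                 time_h = f$obs$times_x,
                 residual_mg = f$obs$obs_x - f$fitted_x),
      data.frame(subject = i, drug = object$drug_labels[["y"]],
                 time_h = f$obs$times_y,
                 residual_mg = f$obs$obs_y - f$fitted_y))
  }))
}

#' @export
plot.coupledpk_fit <- function(x, ...) {
  sys <- .fit_system(x)
  tmax <- max(unlist(lapply(x$stage2, function(f)
    c(f$obs$times_x, f$obs$times_y))))
  tt <- seq(0, tmax, length.out = 200L)
  sim <- .central_both(sys, tt, tt)
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  for (d in c("x", "y")) {
    obs_t <- unlist(lapply(x$stage2, function(f)
      if (d == "x") f$obs$times_x else f$obs$times_y))
    obs_v <- unlist(lapply(x$stage2, function(f)
      if (d == "x") f$obs$obs_x else f$obs$obs_y)) / 1000
    plot(obs_t, obs_v, xlab = "time (h)", ylab = "central amount (10^3 mg)",
         main = x$drug_labels[[d]], ...)
    graphics::lines(tt, if (d == "x") sim$x else sim$y, col = 2)
  }
  invisible(x)
}

#' @param nsim number of replicate datasets to simulate.
#' @param seed RNG seed.
#' @param sd_frac proportional noise scale for simulated observations.
#' @rdname fit_coupled
#' @export
simulate.coupledpk_fit <- function(object, nsim = 1, seed = 1,
                                   sd_frac = 0.1, ...) {
  sys <- .fit_system(object)
  times <- object$stage2[[1L]]$obs$times_x
  make_dataset(sys, "combined",
               noise_spec(sd_frac = sd_frac, n_reps = nsim, seed = seed,
                          times = times))
}
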