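# Fit each replicate dataset once with a derived deterministic seed;
# returns the n_reps x 8 matrix of stage-2 estimates.  `datasets` is a
# list of data frames with columns time, x_obs, y_obs (10^3 mg), as
# produced by add_noise().
.fit_replicates <- function(datasets, system, lambda, control,
                            fix_zero = character()) {
  t(vapply(seq_along(datasets), function(i) {
    obs <- .obs_from_replicate(datasets[[i]])
    ctl <- control
    ctl$seed <- (control$seed + 104729L * i) %% .Machine$integer.max
    fit_interactions(obs, system, lambda = lambda, control = ctl,
                     fix_zero = fix_zero)$W
  }, numeric(8L)))
}

#' Sensitivity of the interaction estimates to the regularization strength
#'
#' Repeats the stage-2 fit over replicate datasets for each value of
#' `lambda` and summarizes every interaction coefficient by its mean
#' and normal-theory 95% confidence interval across replicates.
#'
#' @param datasets list of replicate observation sets (data frames with
#'   columns `time`, `x_obs`, `y_obs` in 10^3 mg), e.g. from
#'   [add_noise()].
#' @param system a [coupled_system()] carrying the stage-1 rates.
#' @param lambdas numeric grid of regularization strengths.
#' @param control a [pso_control()].
#' @return Data frame with columns `lambda`, `parameter`, `mean`,
#'   `ci_lower`, `ci_upper`.
#' @export
lambda_scan <- function(datasets, system, lambdas, control) {
  stopifnot(length(lambdas) >= 1L, length(datasets) >= 1L)
  out <- lapply(lambdas, function(l) {
    E <- .fit_replicates(datasets, system, lambda = l, control = control)
    m <- colMeans(E)
    se <- apply(E, 2L, stats::sd) / sqrt(nrow(E))
    data.frame(lambda = l, parameter = .W_NAMES, mean = m,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Bootstrap the stage-2 interaction estimates over replicate datasets
#'
#' The resampling unit is the replicate dataset: each bootstrap draw
#' selects a dataset with replacement from `datasets` and its statistic
#' is the stage-2 estimate refitted on that dataset (fits are memoised
#' per unique dataset, so each dataset is fitted once).  The bootstrap
#' distribution is therefore the sampling distribution of a
#' single-dataset estimate, and the percentile interval reflects the
#' between-dataset variability.  When `null_values` is supplied, a
#' two-sided percentile p-value of each null value within the bootstrap
#' distribution is reported.
#'
#' @inheritParams lambda_scan
#' @param lambda regularization strength.
#' @param B number of bootstrap draws.
#' @param null_values optional named 8-vector of null interaction
#'   values to test against (e.g. the generating values).
#' @param seed seed for the resampling (fits use `control`'s seed).
#' @param estimates optional precomputed per-dataset estimate matrix
#'   (`length(datasets)` rows, 8 columns) from an earlier run, so the
#'   memoised fits are not recomputed.
#' @return Data frame with columns `parameter`, `mean`, `ci_lower`,
#'   `ci_upper` and, when `null_values` is given, `p_value`.  The
#'   per-dataset estimate matrix is attached as attribute
#'   `"estimates"`.
#' @export
bootstrap_fit <- function(datasets, system, lambda = 0.6, control,
                          B = 200, null_values = NULL, seed = 1,
                          estimates = NULL) {
  stopifnot(length(datasets) >= 2L, B >= 1L)
  E <- if (!is.null(estimates)) {
    stopifnot(nrow(estimates) == length(datasets), ncol(estimates) == 8L)
    estimates
  } else {
    .fit_replicates(datasets, system, lambda = lambda, control = control)
  }
  idx <- .with_preserved_rng(seed,
    sample.int(nrow(E), B, replace = TRUE))
  boot <- E[idx, , drop = FALSE]
  if (all(idx == idx[1L]))
    warning("all bootstrap draws selected the same dataset; ",
            "degenerate confidence intervals")
  m <- colMeans(boot)
  ci <- apply(boot, 2L, stats::quantile, probs = c(0.025, 0.975))
  out <- data.frame(parameter = .W_NAMES, mean = m,
                    ci_lower = ci[1L, ], ci_upper = ci[2L, ],
                    row.names = NULL)
  if (!is.null(null_values)) {
    nv <- null_values[.W_NAMES]
    out$p_value <- vapply(seq_len(8L), function(j) {
      lo <- mean(boot[, j] <= nv[j]); hi <- mean(boot[, j] >= nv[j])
      min(1, 2 * min(lo, hi))
    }, numeric(1L))
  }
  attr(out, "estimates") <- E
  out
}

.ABLATION_MASKS <- list(
  model1 = character(),
  model2 = c("x.g_abs", "y.g_abs"),
  model3 = c("x.g_el", "y.g_el"),
  model4 = c("x.g_abs", "y.g_abs", "x.g_el", "y.g_el"))

#' Interaction-term ablation study
#'
#' Refits the stage-2 model under nested parameter-masking schemes to
#' quantify what the absorption and elimination interaction terms
#' contribute: `model1` keeps all eight coefficients free, `model2`
#' pins the absorption coefficients to zero, `model3` pins the
#' elimination coefficients, and `model4` pins both.  Each scheme
#' reports its per-drug R-squared and least-squares AIC with `k` equal
#' to the number of free coefficients.
#'
#' @param obs a [pk_observations()].
#' @param system a [coupled_system()] with stage-1 rates.
#' @param lambda regularization strength.
#' @param control a [pso_control()].
#' @param schemes subset of `c("model1", "model2", "model3", "model4")`.
#' @return Data frame with one row per scheme: `scheme`, `k_free`,
#'   `sse`, `r2_x`, `r2_y`, `aic`.  The individual fits are attached as
#'   attribute `"fits"`.
#' @export
ablation_study <- function(obs, system, lambda = 0.6, control,
                           schemes = names(.ABLATION_MASKS)) {
  stopifnot(all(schemes %in% names(.ABLATION_MASKS)))
  if (!length(schemes))
    return(data.frame(scheme = character(), k_free = integer(),
                      sse = numeric(), r2_x = numeric(),
                      r2_y = numeric(), aic = numeric()))
  fits <- lapply(schemes, function(sc) {
    fit_interactions(obs, system, lambda = lambda, control = control,
                     fix_zero = .ABLATION_MASKS[[sc]])
  })
  n_tot <- length(obs$obs_x) + length(obs$obs_y)
  out <- data.frame(
    scheme = schemes,
    k_free = vapply(fits, function(f) 8L - length(f$fix_zero),
                    integer(1L)),
    sse = vapply(fits, function(f)
      sum((f$fitted_x - obs$obs_x)^2) + sum((f$fitted_y - obs$obs_y)^2),
      numeric(1L)),
    r2_x = vapply(fits, `[[`, numeric(1L), "r2_x"),
    r2_y = vapply(fits, `[[`, numeric(1L), "r2_y"),
    aic = vapply(fits, `[[`, numeric(1L), "aic"),
    row.names = NULL)
  attr(out, "fits") <- setNames(fits, schemes)
  out
}
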