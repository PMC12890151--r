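#' Control settings for the particle swarm optimizer
#'
#' Standard constriction-coefficient PSO settings (inertia 0.7298,
#' cognitive = social = 1.49618) with clamp-to-bound constraint
#' handling.  A seed is mandatory: given identical settings and data
#' the optimizer is bit-reproducible.  By default the swarm optimum is
#' polished by a bounded quasi-Newton step (`optim(method =
#' "L-BFGS-B")`), which sharpens convergence near the basin the swarm
#' found without affecting global exploration.
#'
#' @param swarm number of particles (>= 2).
#' @param maxit maximum iterations.
#' @param inertia inertia weight.
#' @param cognitive,social acceleration coefficients.
#' @param vmax_frac velocity clamp as a fraction of each box width.
#' @param patience iterations without meaningful improvement before the
#'   swarm stops early (the polish step still runs).
#' @param abstol,reltol an iteration counts as stalled when the best
#'   objective improves by less than `abstol + reltol * |best|`.
#' @param polish logical; run a local L-BFGS-B refinement from the
#'   swarm best.
#' @param seed RNG seed (mandatory).
#' @return An object of class `pso_control`.
#' @export
pso_control <- function(swarm = 30, maxit = 150, inertia = 0.7298,
                        cognitive = 1.49618, social = 1.49618,
                        vmax_frac = 0.5, patience = 30, abstol = 1e-9,
                        reltol = 1e-6, polish = TRUE, seed) {
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is required for a reproducible PSO run", call. = FALSE)
  if (swarm < 2) stop("'swarm' must be at least 2", call. = FALSE)
  if (cognitive <= 0 || social <= 0)
    stop("acceleration coefficients must be positive", call. = FALSE)
  structure(list(swarm = as.integer(swarm), maxit = as.integer(maxit),
                 inertia = inertia, cognitive = cognitive,
                 social = social, vmax_frac = vmax_frac,
                 patience = as.integer(patience), abstol = abstol,
                 reltol = reltol,
                 polish = isTRUE(polish), seed = as.integer(seed)),
            class = "pso_control")
}

#' Box-constrained particle swarm minimization
#'
#' Global minimization of `fn` over a rectangular box by
#' constriction-type particle swarm optimization with positions clamped
#' to the bounds, optionally followed by a local L-BFGS-B polish.
#' Deterministic for a given [pso_control()] seed; the caller's RNG
#' state is preserved.
#'
#' @param fn objective, a function of a numeric vector.
#' @param lower,upper numeric bound vectors of equal length.
#' @param control a [pso_control()].
#' @return List with elements `par`, `value`, `iterations`,
#'   `evaluations`, and `trace` (best objective per iteration).
#' @examples
#' sphere <- function(p) sum((p - 1:2)^2)
#' pso_optim(sphere, c(-5, -5), c(5, 5),
#'           pso_control(swarm = 20, maxit = 100, seed = 1))
#' @export
pso_optim <- function(fn, lower, upper, control) {
  stopifnot(inherits(control, "pso_control"),
            length(lower) == length(upper), all(upper > lower))
  d <- length(lower)
  width <- upper - lower
  vmax <- control$vmax_frac * width
  evals <- 0L
  fwrap <- function(p) {
    evals <<- evals + 1L
    v <- fn(p)
    if (!is.finite(v)) 1e12 else v
  }

  .with_preserved_rng(control$seed, {
    pos <- matrix(stats::runif(control$swarm * d), control$swarm, d)
    pos <- sweep(sweep(pos, 2L, width, "*"), 2L, lower, "+")
    pos[1L, ] <- pmin(pmax(0, lower), upper)  # include the null coupling
    vel <- matrix(stats::runif(control$swarm * d, -1, 1), control$swarm, d)
    vel <- sweep(vel, 2L, 0.1 * width, "*")

    pbest <- pos
    pval <- apply(pos, 1L, fwrap)
    g <- which.min(pval)
    gbest <- pos[g, ]; gval <- pval[g]
    trace <- numeric(control$maxit)
    stall <- 0L; it <- 0L

    while (it < control$maxit) {
      it <- it + 1L
      r1 <- matrix(stats::runif(control$swarm * d), control$swarm, d)
      r2 <- matrix(stats::runif(control$swarm * d), control$swarm, d)
      G <- matrix(gbest, control$swarm, d, byrow = TRUE)
      vel <- control$inertia * vel +
        control$cognitive * r1 * (pbest - pos) +
        control$social * r2 * (G - pos)
      vel <- pmin(pmax(vel, matrix(-vmax, control$swarm, d, byrow = TRUE)),
                  matrix(vmax, control$swarm, d, byrow = TRUE))
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lower, control$swarm, d, byrow = TRUE)),
                  matrix(upper, control$swarm, d, byrow = TRUE))
      val <- apply(pos, 1L, fwrap)
      improved <- val < pval
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pval[improved] <- val[improved]
      g <- which.min(pval)
      thresh <- control$abstol + control$reltol * abs(gval)
      if (pval[g] < gval - thresh) stall <- 0L else stall <- stall + 1L
      if (pval[g] < gval) {
        gval <- pval[g]; gbest <- pbest[g, ]
      }
      trace[it] <- gval
      if (stall >= control$patience) break
    }

    if (control$polish) {
      pol <- tryCatch(
        stats::optim(gbest, fwrap, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 200L, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= gval) {
        gbest <- pol$par; gval <- pol$value
      }
    }
    list(par = unname(gbest), value = gval, iterations = it,
         evaluations = evals, trace = trace[seq_len(it)])
  })
}
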