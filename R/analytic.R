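#' Closed-form central amount of the uncoupled oral two-compartment model
#'
#' When a drug is given alone (all interaction coefficients zero) the
#' model reduces to the standard oral two-compartment system, whose
#' central-compartment amount has the tri-exponential closed form
#' \deqn{x_1(t) = k_a D \left[ \frac{(k_{pc}-\lambda_1)e^{-\lambda_1 t}}
#'   {(k_a-\lambda_1)(\lambda_2-\lambda_1)} +
#'   \frac{(k_{pc}-\lambda_2)e^{-\lambda_2 t}}
#'   {(k_a-\lambda_2)(\lambda_1-\lambda_2)} +
#'   \frac{(k_{pc}-k_a)e^{-k_a t}}
#'   {(\lambda_1-k_a)(\lambda_2-k_a)} \right]}
#' with hybrid constants \eqn{\lambda_{1,2}} the roots of
#' \eqn{s^2 + (k_{cp}+k_{pc}+k_{el})s + k_{pc}k_{el} = 0}.  The two
#' hybrid constants are always distinct for strictly positive rates.
#' When `k_abs` equals `k_pc` the third coefficient cancels
#' algebraically (its numerator is zero); when `k_abs` falls within
#' tolerance of a hybrid constant the closed form is ill-conditioned and
#' the function evaluates the limit through the matrix exponential of
#' the linear system instead.
#'
#' This function is the analytic oracle against which the numerical
#' integrator is validated; it never calls the ODE solver.
#'
#' @param rates named numeric vector with elements `k_abs`, `k_cp`,
#'   `k_pc`, `k_el` (h^-1), or a [drug_spec()] whose rates are used.
#' @param dose initial gut amount, 10^3 mg.
#' @param times numeric vector of times (h), each >= 0.
#' @return Numeric vector of central-compartment amounts (10^3 mg) at
#'   `times`.  The hybrid constants are attached as attribute
#'   `"lambda"`.
#' @examples
#' analytic_uncoupled(c(k_abs = 0.5, k_cp = 0.5, k_pc = 0.5, k_el = 0.5),
#'                    dose = 0.6, times = c(0, 1, 2, 4))
#' @export
analytic_uncoupled <- function(rates, dose, times) {
  if (inherits(rates, "drug_spec")) {
    if (missing(dose)) dose <- rates$dose
    rates <- rates$rates
  }
  stopifnot(all(c("k_abs", "k_cp", "k_pc", "k_el") %in% names(rates)),
            all(rates > 0), dose >= 0, all(times >= 0))
  ka <- rates[["k_abs"]]; kcp <- rates[["k_cp"]]
  kpc <- rates[["k_pc"]]; kel <- rates[["k_el"]]
  b <- kcp + kpc + kel
  disc <- sqrt(b^2 - 4 * kpc * kel)   # > 0 for positive rates
  l1 <- (b - disc) / 2
  l2 <- (b + disc) / 2

  degenerate <- min(abs(ka - l1), abs(ka - l2)) < 1e-7 * max(ka, l2)
  if (!degenerate) {
    a1 <- (kpc - l1) / ((ka - l1) * (l2 - l1))
    a2 <- (kpc - l2) / ((ka - l2) * (l1 - l2))
    a3 <- (kpc - ka) / ((l1 - ka) * (l2 - ka))
    x1 <- ka * dose *
      (a1 * exp(-l1 * times) + a2 * exp(-l2 * times) + a3 * exp(-ka * times))
  } else {
    # k_abs coincides with a hybrid constant: evaluate the limit via the
    # matrix exponential of the 3-compartment linear system.
    A <- matrix(c(-ka,        0,    0,
                   ka, -(kcp + kel),  kpc,
                    0,       kcp,  -kpc), 3L, 3L, byrow = TRUE)
    x1 <- vapply(times, function(t) {
      (.expm(A * t) %*% c(dose, 0, 0))[2L]
    }, numeric(1L))
  }
  x1 <- pmax(x1, 0)  # clip -0-scale roundoff at t = 0
  attr(x1, "lambda") <- c(lambda1 = l1, lambda2 = l2)
  x1
}

# Small dense matrix exponential by scaling-and-squaring on the Taylor
# series; adequate for the well-conditioned 3x3 rate matrices used in
# the degenerate-case limit above.
.expm <- function(A) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1, norm(A, "1")))))
  A <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:20) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

.CONC_UNIT_FACTORS <- c(
  "10^3mg/ml" = 1, "g/ml" = 1, "mg/ml" = 1e-3,
  "ug/ml" = 1e-6, "ng/ml" = 1e-9)

# Multiplier taking a concentration in `unit` to (10^3 mg)/ml.
.conc_unit_factor <- function(unit) {
  f <- .CONC_UNIT_FACTORS[unit]
  if (is.na(f))
    stop("unknown concentration unit '", unit, "'; known units: ",
         paste(names(.CONC_UNIT_FACTORS), collapse = ", "), call. = FALSE)
  unname(f)
}

#' Convert between plasma concentration and central-compartment amount
#'
#' The apparent central volume Vc relates the measured plasma
#' concentration to the amount of drug in the central compartment via
#' `amount = Vc * concentration`.  Concentrations are converted from
#' their declared unit into the package's canonical amount scale
#' (10^3 mg).
#'
#' @param concentration numeric vector of non-negative concentrations.
#' @param v_central apparent central volume, ml; must be positive.
#' @param unit concentration unit, one of `"10^3mg/ml"` (canonical),
#'   `"g/ml"`, `"mg/ml"`, `"ug/ml"`, `"ng/ml"`.
#' @return For `amount_from_concentration`, amounts in 10^3 mg; for
#'   `concentration_from_amount`, concentrations in `unit`.
#' @examples
#' amount_from_concentration(1e-5, v_central = 4163.137)
#' @export
amount_from_concentration <- function(concentration, v_central,
                                      unit = "10^3mg/ml") {
  if (is.null(v_central) || !is.numeric(v_central) || v_central <= 0)
    stop("'v_central' (ml) must be supplied and positive", call. = FALSE)
  if (any(concentration < 0, na.rm = TRUE))
    stop("concentrations must be non-negative", call. = FALSE)
  concentration * .conc_unit_factor(unit) * v_central
}

#' @param amount numeric vector of amounts, 10^3 mg.
#' @rdname amount_from_concentration
#' @export
concentration_from_amount <- function(amount, v_central,
                                      unit = "10^3mg/ml") {
  if (is.null(v_central) || !is.numeric(v_central) || v_central <= 0)
    stop("'v_central' (ml) must be supplied and positive", call. = FALSE)
  amount / v_central / .conc_unit_factor(unit)
}
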