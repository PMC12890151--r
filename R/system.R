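#' Specify one drug's dose, rate constants and interaction coefficients
#'
#' A `drug_spec` bundles everything the coupled model needs to know about
#' one drug: the oral dose placed in the gut compartment at `t = 0`, the
#' four first-order rate constants of the standard two-compartment oral
#' model, the four interaction coefficients through which the partner
#' drug's amounts modify those rates, and (optionally) the apparent
#' central volume used to convert plasma concentration to amount.
#'
#' Amounts are on the package's canonical 10^3 mg scale and time is in
#' hours, so rates are h^-1 and interaction coefficients are
#' 10^3/(mg h).  Interaction coefficients may take either sign: a
#' negative coefficient is an antagonistic (inhibitory) coupling, a
#' positive one promotes the corresponding process.
#'
#' @param dose initial gut amount, 10^3 mg; non-negative.
#' @param k_abs,k_cp,k_pc,k_el first-order rate constants (h^-1) for
#'   absorption, central-to-peripheral transfer, peripheral-to-central
#'   transfer and elimination; all strictly positive.
#' @param g_abs,g_cp,g_pc,g_el interaction coefficients modifying the
#'   four rates linearly in the partner drug's amount (10^3/(mg h)).
#'   `g_abs` is driven by the partner's gut amount, `g_cp` and `g_el` by
#'   the partner's central amount, `g_pc` by the partner's peripheral
#'   amount.
#' @param v_central apparent central-compartment volume (ml), used only
#'   for concentration/amount conversion; may be `NULL` until a
#'   monotherapy fit supplies it.
#' @return An object of class `drug_spec`.
#' @seealso [coupled_system()], [make_scenario()]
#' @examples
#' drug_spec(dose = 0.6, k_abs = 0.5, k_cp = 0.5, k_pc = 0.5, k_el = 0.5)
#' @export
drug_spec <- function(dose, k_abs, k_cp, k_pc, k_el,
                      g_abs = 0, g_cp = 0, g_pc = 0, g_el = 0,
                      v_central = NULL) {
  rates <- c(k_abs = k_abs, k_cp = k_cp, k_pc = k_pc, k_el = k_el)
  inter <- c(g_abs = g_abs, g_cp = g_cp, g_pc = g_pc, g_el = g_el)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("'dose' must be a single finite non-negative number", call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("rate constants must all be strictly positive and finite",
         call. = FALSE)
  if (any(!is.finite(inter)))
    stop("interaction coefficients must be finite", call. = FALSE)
  if (!is.null(v_central)) {
    if (!is.numeric(v_central) || length(v_central) != 1L ||
        !is.finite(v_central) || v_central <= 0)
      stop("'v_central' must be a single positive number (ml)",
           call. = FALSE)
  }
  structure(list(dose = dose, rates = rates, interactions = inter,
                 v_central = v_central),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat("Drug specification (amounts in 10^3 mg, time in h)\n")
  cat("  dose:", format(x$dose), "\n")
  cat("  rates (h^-1):        ",
      paste(names(x$rates), format(x$rates, digits = 5), sep = "=",
            collapse = "  "), "\n")
  cat("  interactions (10^3/(mg h)):",
      paste(names(x$interactions), format(x$interactions, digits = 5),
            sep = "=", collapse = "  "), "\n")
  if (!is.null(x$v_central))
    cat("  Vc (ml):", format(x$v_central), "\n")
  invisible(x)
}

#' Couple two drug specifications into one interacting system
#'
#' Wires two [drug_spec()] objects into the coupled ODE system in which
#' each of drug X's rate constants is modified linearly by drug Y's
#' current amount in the driving compartment, and symmetrically for Y.
#'
#' @param drug_x,drug_y [drug_spec()] objects.
#' @return An object of class `coupled_system`.
#' @examples
#' sys <- coupled_system(
#'   drug_spec(0.6, 0.5, 0.5, 0.5, 0.5),
#'   drug_spec(1.0, 0.6, 0.5, 0.4, 0.3))
#' @export
coupled_system <- function(drug_x, drug_y) {
  stopifnot(inherits(drug_x, "drug_spec"), inherits(drug_y, "drug_spec"))
  structure(list(drug_x = drug_x, drug_y = drug_y),
            class = "coupled_system")
}

#' @export
print.coupled_system <- function(x, ...) {
  cat("Coupled two-compartment oral PK system\n\n-- drug X --\n")
  print(x$drug_x)
  cat("\n-- drug Y --\n")
  print(x$drug_y)
  invisible(x)
}

# Flatten a coupled_system into the 16-parameter vector consumed by the
# compiled RHS: (X rates, X interactions, Y rates, Y interactions).
.system_parms <- function(system) {
  c(system$drug_x$rates, system$drug_x$interactions,
    system$drug_y$rates, system$drug_y$interactions)
}

# Interaction coefficients as the flat 8-vector W (X first, then Y).
.system_W <- function(system) {
  w <- c(system$drug_x$interactions, system$drug_y$interactions)
  names(w) <- .W_NAMES
  w
}

# Return a copy of `system` with interaction vector W (length 8,
# ordered as .W_NAMES) installed.
.set_W <- function(system, W) {
  stopifnot(length(W) == 8L)
  system$drug_x$interactions[] <- W[1:4]
  system$drug_y$interactions[] <- W[5:8]
  system
}

#' Swap the drug labels of a coupled system
#'
#' Relabels drug X as drug Y and vice versa.  Because the model is
#' symmetric under relabelling, simulating the swapped system yields the
#' original trajectories with the x and y columns exchanged.
#'
#' @param system a [coupled_system()].
#' @return The relabelled `coupled_system`.
#' @export
swap_drugs <- function(system) {
  stopifnot(inherits(system, "coupled_system"))
  coupled_system(system$drug_y, system$drug_x)
}
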