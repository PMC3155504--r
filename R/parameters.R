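#' T-cell model parameters
#'
#' Rate constants and Hill constants of the Teff--Treg cross-regulation
#' system. Defaults are the published reference values of the model:
#' activation delta = 1/day (mean 24 h residence in the resting pool),
#' anergy/death of resting cells beta = 0.01/day, return to the resting
#' ("memory") state eta = 0.01/day, clearance gamma_E = gamma_R = 0.2/day
#' (5-day permanence expectancy), half-maximal population sizes k_E = 1000
#' and k_R = 200 cells, Hill coefficient h = 5. The maximum proliferation
#' rates alpha_E and alpha_R are the regime knobs: alpha_E = 2, alpha_R = 1
#' is the healthy preset and alpha_R = 0.25 the autoimmune preset.
#'
#' @param delta activation rate by antigen presentation, 1/day.
#' @param beta rate at which resting cells become anergic or die, 1/day.
#' @param eta rate of return of activated cells to the resting state, 1/day.
#' @param alpha_E maximum Teff proliferation rate, 1/day.
#' @param alpha_R maximum Treg proliferation/activation rate, 1/day.
#' @param gamma_E Teff death/anergy/migration rate, 1/day. The realised Teff
#'   loss is `gamma_E * (1 + hill_up(R, k_R, h))`: Treg presence raises the
#'   clearance above this baseline.
#' @param gamma_R Treg death/anergy/migration rate, 1/day (Teff-independent).
#' @param k_E Teff population size with half-maximal effect on Treg, cells.
#' @param k_R Treg population size with half-maximal effect on Teff, cells.
#' @param hill_h Hill coefficient (response steepness), dimensionless, >= 1.
#' @return an object of class `model_parameters` (named list).
#' @examples
#' p <- model_parameters(alpha_R = 0.25) # autoimmune loop strength
#' p$gamma_E
#' @export
model_parameters <- function(delta = 1, beta = 0.01, eta = 0.01,
                             alpha_E = 2, alpha_R = 1,
                             gamma_E = 0.2, gamma_R = 0.2,
                             k_E = 1000, k_R = 200, hill_h = 5) {
  p <- list(delta = delta, beta = beta, eta = eta,
            alpha_E = alpha_E, alpha_R = alpha_R,
            gamma_E = gamma_E, gamma_R = gamma_R,
            k_E = k_E, k_R = k_R, hill_h = hill_h)
  for (nm in names(p)) check_scalar(p[[nm]], nm, positive = TRUE)
  if (hill_h < 1) stop_domain("hill_h must be >= 1")
  structure(p, class = "model_parameters")
}

#' Tissue damage parameters
#'
#' Activated Teff drive tissue damage through the second-order term
#' `E' = (E/a)^2`. Reversible damage `l` is produced at rate `d1 * E'`,
#' recovers at rate `r`, and converts into irreversible damage `L` at rate
#' `d2`; `L` never decreases. Damage is an output compartment with no
#' feedback on the T-cell populations.
#'
#' @param d1 reversible damage production rate, 1/day.
#' @param d2 irreversible damage (conversion) rate, 1/day.
#' @param a threshold population size scaling the damage drive, cells.
#' @param r recovery rate of reversible damage, 1/day.
#' @return an object of class `damage_parameters`.
#' @export
damage_parameters <- function(d1 = 1, d2 = 0.02, a = 22800, r = 0.1) {
  p <- list(d1 = d1, d2 = d2, a = a, r = r)
  for (nm in names(p)) check_scalar(p[[nm]], nm, positive = TRUE)
  structure(p, class = "damage_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Teff-Treg model parameters (1/day unless noted):\n")
  cat(sprintf("  delta=%g beta=%g eta=%g\n", x$delta, x$beta, x$eta))
  cat(sprintf("  alpha_E=%g alpha_R=%g gamma_E=%g gamma_R=%g\n",
              x$alpha_E, x$alpha_R, x$gamma_E, x$gamma_R))
  cat(sprintf("  k_E=%g cells, k_R=%g cells, hill_h=%g\n",
              x$k_E, x$k_R, x$hill_h))
  invisible(x)
}

#' @export
print.damage_parameters <- function(x, ...) {
  cat(sprintf("Damage parameters: d1=%g d2=%g r=%g (1/day), a=%g cells\n",
              x$d1, x$d2, x$r, x$a))
  invisible(x)
}

# Which transcription of the governing equations is active. The structural
# fallback follows the documented loop structure: Treg raise Teff clearance
# above its 5-day baseline, Treg clearance is constant, damage recovers at r
# and converts irreversibly at d2.
#' Model definition form
#'
#' Identifies the active transcription of the governing equations.
#' @return a character string.
#' @export
model_form <- function() "structural-fallback"

# Flatten parameter objects for the compiled core.
core_pars <- function(params, damage, inflow_E = 0, inflow_R = 0) {
  c(unclass(params), unclass(damage),
    list(inflow_E = inflow_E, inflow_R = inflow_R))
}
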