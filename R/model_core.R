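#' Hill activation and inhibition functions
#'
#' Sigmoidal cross-regulation responses. `hill_up(x, k, h)` is the increasing
#' form `x^h / (k^h + x^h)` (how strongly a population of size `x` stimulates
#' its counterpart); `hill_down(x, k, h) = k^h / (k^h + x^h)` is its
#' complement (how strongly it inhibits). Both are evaluated in a ratio form
#' that stays finite for arbitrarily large `x`.
#'
#' @param x population size, cells (vectorised), >= 0.
#' @param k population size of half-maximal effect, cells, > 0.
#' @param h Hill coefficient, >= 1.
#' @return a numeric vector of fractions; `hill_up` in `[0, 1)`, `hill_down`
#'   in `(0, 1]`, and `hill_up + hill_down == 1`.
#' @examples
#' hill_up(200, 200, 5)   # 0.5 at the half-max point
#' hill_up(400, 200, 5)   # 32/33
#' hill_down(400, 200, 5) # 1/33
#' @export
hill_up <- function(x, k, h) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(h, "h")
  if (h < 1) stop_domain("h must be >= 1")
  if (any(!is.finite(x)) || any(x < 0)) stop_domain("x must be >= 0")
  ifelse(x == 0, 0, 1 / (1 + (k / x)^h))
}

#' @rdname hill_up
#' @export
hill_down <- function(x, k, h) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(h, "h")
  if (h < 1) stop_domain("h must be >= 1")
  if (any(!is.finite(x)) || any(x < 0)) stop_domain("x must be >= 0")
  ifelse(x == 0, 1, 1 / (1 + (x / k)^h))
}

#' T-cell state constructor
#'
#' @param E_r,R_r resting Teff / Treg, cells.
#' @param E,R activated Teff / Treg, cells.
#' @return named numeric vector of class `tcell_state`.
#' @export
tcell_state <- function(E_r = 0, R_r = 0, E = 1000, R = 200) {
  s <- c(E_r = E_r, R_r = R_r, E = E, R = R)
  if (any(!is.finite(s)) || any(s < 0))
    stop_domain("all state components must be finite and >= 0")
  structure(s, class = "tcell_state")
}

#' Rates of change of the four T-cell populations
#'
#' The governing equations of the Teff--Treg loop. Resting pools gain the
#' stochastic inflow and the memory return `eta * activated`, and lose
#' activation (`delta`) and anergy (`beta`). Activated Teff gain
#' `delta * E_r` plus proliferation `alpha_E * E` inhibited by Treg through
#' `hill_down(R, k_R, h)`, and are cleared at `gamma_E * E` raised by Treg
#' through `(1 + hill_up(R, k_R, h))`. Activated Treg gain `delta * R_r`
#' plus proliferation `alpha_R * R` stimulated by Teff through
#' `hill_up(E, k_E, h)`, and are cleared at the constant rate `gamma_R`.
#' Both activated pools lose `eta` to the resting (memory) state.
#'
#' @param state a [tcell_state()] or named numeric vector
#'   `(E_r, R_r, E, R)`, all components >= 0.
#' @param params a [model_parameters()] object.
#' @param inflow instantaneous resting-cell influx, named numeric
#'   `c(i_E = , i_R = )` in cells/day (defaults to zero; the stochastic
#'   pulse trains are realised as state jumps, not rates).
#' @return named numeric vector of rates `(E_r, R_r, E, R)`, cells/day.
#' @export
tcell_derivatives <- function(state, params, inflow = c(i_E = 0, i_R = 0)) {
  s <- unclass(state)
  if (length(s) != 4 || any(!is.finite(s)) || any(s < 0))
    stop_domain("state must be four finite non-negative components")
  iE <- inflow[["i_E"]]; iR <- inflow[["i_R"]]
  if (iE < 0 || iR < 0) stop_domain("inflow must be non-negative")
  E_r <- s[[1]]; R_r <- s[[2]]; E <- s[[3]]; R <- s[[4]]
  p <- params
  c(E_r = iE - (p$delta + p$beta) * E_r + p$eta * E,
    R_r = iR - (p$delta + p$beta) * R_r + p$eta * R,
    E = p$delta * E_r + p$alpha_E * E * hill_down(R, p$k_R, p$hill_h) -
        p$gamma_E * E * (1 + hill_up(R, p$k_R, p$hill_h)) - p$eta * E,
    R = p$delta * R_r + p$alpha_R * R * hill_up(E, p$k_E, p$hill_h) -
        p$gamma_R * R - p$eta * R)
}

#' Rates of change of the tissue damage compartments
#'
#' Damage is driven by the second-order effect of activated Teff,
#' `E' = (E/a)^2`: reversible damage obeys
#' `dl/dt = d1 * E' - (r + d2) * l` and irreversible damage accrues as
#' `dL/dt = d2 * l` (never negative). One-way coupling: damage does not feed
#' back on the T-cell populations.
#'
#' @param E activated Teff count, cells, >= 0.
#' @param damage named numeric `c(l = , L = )`, both >= 0.
#' @param damage_params a [damage_parameters()] object.
#' @return named numeric vector of rates `(l, L)`, damage units/day.
#' @export
damage_derivatives <- function(E, damage, damage_params = damage_parameters()) {
  check_scalar(E, "E", nonneg = TRUE)
  l <- damage[["l"]]; L <- damage[["L"]]
  if (l < 0 || L < 0) stop_domain("damage components must be >= 0")
  dp <- damage_params
  Eprime <- (E / dp$a)^2
  c(l = dp$d1 * Eprime - (dp$r + dp$d2) * l,
    L = dp$d2 * l)
}
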