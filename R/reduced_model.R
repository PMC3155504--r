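#' Rates of the reduced two-variable model
#'
#' The deterministic reduction keeps only the activated pools `E` and `R`
#' and replaces the resting-cell influx by its expected value
#' `(Lambda_E, Lambda_R)` (see [expected_inflow()]):
#' `dE/dt = Lambda_E + alpha_E E hill_down(R) - gamma_E E (1 + hill_up(R)) - eta E`,
#' `dR/dt = Lambda_R + alpha_R R hill_up(E) - gamma_R R - eta R`.
#'
#' @param E,R activated Teff / Treg, cells, >= 0.
#' @param params a [model_parameters()] object.
#' @param inflow named numeric `c(lambda_E = , lambda_R = )`, cells/day;
#'   defaults to the expected inflow of the default pulse spec so the full
#'   and reduced models describe the same average forcing.
#' @return named numeric `c(dE = , dR = )`, cells/day.
#' @export
reduced_derivatives <- function(E, R, params = model_parameters(),
                                inflow = expected_inflow()) {
  check_scalar(E, "E", nonneg = TRUE)
  check_scalar(R, "R", nonneg = TRUE)
  v <- reduced_rates_core(E, R, core_pars(params, damage_parameters()),
                          inflow[["lambda_E"]], inflow[["lambda_R"]])
  c(dE = v[1], dR = v[2])
}

# Numerical Jacobian of the reduced field by central differences.
reduced_jacobian <- function(E, R, params, inflow, rel_step = 1e-6) {
  f <- function(x) {
    v <- reduced_rates_core(max(x[1], 0), max(x[2], 0),
                            core_pars(params, damage_parameters()),
                            inflow[["lambda_E"]], inflow[["lambda_R"]])
    c(v[1], v[2])
  }
  x <- c(E, R)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    hstep <- rel_step * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + hstep
    xm <- x; xm[j] <- x[j] - hstep
    J[, j] <- (f(xp) - f(xm)) / (2 * hstep)
  }
  J
}

#' Find the equilibrium of the reduced model
#'
#' Damped Newton iteration on the two-variable field, with a long-horizon
#' integration restart when Newton stalls. The model has a single attracting
#' equilibrium for loop strengths in the working range, and the result does
#' not depend on the initial guess; for very strong Treg proliferation
#' (relative to the forcing) the Treg balance cannot close and the solver
#' reports non-convergence.
#'
#' @param params a [model_parameters()] object.
#' @param inflow expected inflow, `c(lambda_E = , lambda_R = )`.
#' @param initial_guess numeric `c(E, R)` starting point.
#' @param tol residual tolerance, cells/day.
#' @param max_iter Newton iteration cap.
#' @return an object of class `equilibrium`: list with `E_star`, `R_star`,
#'   `residual` (max absolute rate at the point), `classification`
#'   (`"stable spiral"`, `"stable node"` or `"unstable"`, from the Jacobian
#'   eigenvalues) and `eigenvalues`.
#' @export
find_equilibrium <- function(params = model_parameters(),
                             inflow = expected_inflow(),
                             initial_guess = c(E = 1000, R = 200),
                             tol = 1e-8, max_iter = 200) {
  cp <- core_pars(params, damage_parameters())
  lE <- inflow[["lambda_E"]]; lR <- inflow[["lambda_R"]]
  rate <- function(x) {
    v <- reduced_rates_core(x[1], x[2], cp, lE, lR)
    c(v[1], v[2])
  }
  newton <- function(x0) {
    x <- pmax(as.numeric(x0), c(1e-6, 1e-6))
    for (it in seq_len(max_iter)) {
      fx <- rate(x)
      if (max(abs(fx)) < tol) return(list(x = x, ok = TRUE))
      J <- reduced_jacobian(x[1], x[2], params, inflow)
      step <- tryCatch(solve(J, -fx), error = function(e) NULL)
      if (is.null(step)) return(list(x = x, ok = FALSE))
      lambda <- 1
      repeat {
        xn <- pmax(x + lambda * step, c(1e-9, 1e-9))
        if (max(abs(rate(xn))) < max(abs(fx)) || lambda < 1e-6) break
        lambda <- lambda / 2
      }
      if (lambda < 1e-6) return(list(x = x, ok = FALSE))
      x <- xn
    }
    list(x = x, ok = max(abs(rate(x))) < tol)
  }
  sol <- newton(initial_guess)
  if (!sol$ok) {
    # integrate toward the attractor, then retry Newton from there; the
    # integration itself overflows when no finite attractor exists
    path <- tryCatch(
      reduced_euler_core(max(initial_guess[1], 1), max(initial_guess[2], 1),
                         cp, lE, lR,
                         n_steps = 200000L, dt = 0.05,
                         record_stride = 200000L),
      error = function(e) NULL)
    if (!is.null(path))
      sol <- newton(c(path[nrow(path), 3], path[nrow(path), 2]))
  }
  if (!sol$ok) {
    fx <- rate(sol$x)
    stop_domain(sprintf(
      "equilibrium solver did not converge (residual %.3g at E=%.3g, R=%.3g); the Treg balance may not close for these parameters",
      max(abs(fx)), sol$x[1], sol$x[2]))
  }
  x <- sol$x
  J <- reduced_jacobian(x[1], x[2], params, inflow)
  ev <- eigen(J, only.values = TRUE)$values
  cls <- if (all(Re(ev) < 0)) {
    if (any(abs(Im(ev)) > 1e-12)) "stable spiral" else "stable node"
  } else "unstable"
  structure(list(E_star = x[1], R_star = x[2],
                 residual = max(abs(rate(x))),
                 classification = cls, eigenvalues = ev),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium: E* = %.4g, R* = %.4g cells (%s; residual %.2g)\n",
              x$E_star, x$R_star, x$classification, x$residual))
  invisible(x)
}

#' Deterministic phase-plane trajectory of the reduced model
#'
#' Fixed-step integration of the two-variable system. In the working
#' parameter range the path spirals clockwise in the (R, E) plane toward the
#' equilibrium, with spirals elongating along the E axis as alpha_R
#' decreases.
#'
#' @param params a [model_parameters()] object.
#' @param inflow expected inflow.
#' @param start numeric `c(E = , R = )` starting state.
#' @param duration days.
#' @param dt step, days.
#' @param record_stride record every n-th step.
#' @return a data frame `(time, R, E)` (ordered path in the phase plane).
#' @export
phase_trajectory <- function(params = model_parameters(),
                             inflow = expected_inflow(),
                             start = c(E = 1000, R = 200),
                             duration = 365, dt = 0.05, record_stride = 1L) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  n_steps <- as.integer(round(duration / dt))
  rec <- reduced_euler_core(start[["E"]], start[["R"]],
                            core_pars(params, damage_parameters()),
                            inflow[["lambda_E"]], inflow[["lambda_R"]],
                            n_steps, dt, as.integer(record_stride))
  data.frame(time = rec[, 1], R = rec[, 2], E = rec[, 3])
}

#' Classify the phase-plane sector of a state
#'
#' Sectors are the sign quadrants of the growth rates `(dE/dt, dR/dt)`:
#' I = both populations growing (+,+); II = Teff diminishing, Treg growing
#' (-,+); III = both diminishing (-,-); IV = Teff growing, Treg diminishing
#' (+,-). States on a sector boundary (a rate within `tol` of zero, e.g. the
#' equilibrium) are not assigned and raise an error.
#'
#' @param E,R activated Teff / Treg, cells.
#' @param params a [model_parameters()] object.
#' @param inflow expected inflow.
#' @param tol rate magnitude below which the sector is indeterminate,
#'   cells/day.
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_sector <- function(E, R, params = model_parameters(),
                            inflow = expected_inflow(), tol = 1e-9) {
  v <- reduced_derivatives(E, R, params, inflow)
  if (any(abs(v) <= tol))
    stop_domain("indeterminate sector: a growth rate is zero within tolerance")
  if (v[["dE"]] > 0 && v[["dR"]] > 0) "I"
  else if (v[["dE"]] < 0 && v[["dR"]] > 0) "II"
  else if (v[["dE"]] < 0 && v[["dR"]] < 0) "III"
  else "IV"
}

# Vectorised sector labels along a trajectory; NA on boundaries. Used by the
# therapy timing rules.
sector_labels <- function(E, R, params, inflow, tol = 1e-9) {
  cp <- core_pars(params, damage_parameters())
  lE <- inflow[["lambda_E"]]; lR <- inflow[["lambda_R"]]
  vapply(seq_along(E), function(i) {
    v <- reduced_rates_core(E[i], R[i], cp, lE, lR)
    if (any(abs(v) <= tol)) return(NA_character_)
    if (v[1] > 0 && v[2] > 0) "I"
    else if (v[1] < 0 && v[2] > 0) "II"
    else if (v[1] < 0 && v[2] < 0) "III"
    else "IV"
  }, character(1))
}

#' Export a phase portrait as a delimited table
#'
#' Writes `(time, R, E, sector)` tab-separated; sector is `NA` on boundaries.
#'
#' @param path output path.
#' @inheritParams phase_trajectory
#' @return the written data frame, invisibly.
#' @export
write_phase_portrait <- function(path, params = model_parameters(),
                                 inflow = expected_inflow(),
                                 start = c(E = 1000, R = 200),
                                 duration = 365, dt = 0.05,
                                 record_stride = 20L) {
  df <- phase_trajectory(params, inflow, start, duration, dt, record_stride)
  df$sector <- sector_labels(df$E, df$R, params, inflow)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
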