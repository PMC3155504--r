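#' Specification of the stochastic resting-cell forcing
#'
#' The model is forced by trains of 100 randomly distributed impulses per
#' year of newly produced resting Teff and resting Treg cells, with
#' independent random streams for the two populations. The impulse amplitude
#' (cells added per impulse) is a convention of this package; see the
#' methods vignette for the calibration rationale.
#'
#' @param rate_E,rate_R impulses per year for the Teff / Treg trains.
#' @param amplitude_E,amplitude_R cells added per impulse.
#' @param scheme `"fixed"` (default): each realisation carries exactly
#'   `round(rate * duration / 365)` impulses at independent uniform times,
#'   matching the fixed-frequency description of the forcing; `"poisson"`:
#'   the impulse count is Poisson with the same mean (robustness option).
#' @return an object of class `pulse_spec`.
#' @export
pulse_spec <- function(rate_E = 100, rate_R = 100,
                       amplitude_E = 400, amplitude_R = 40,
                       scheme = c("fixed", "poisson")) {
  scheme <- match.arg(scheme)
  check_scalar(rate_E, "rate_E", nonneg = TRUE)
  check_scalar(rate_R, "rate_R", nonneg = TRUE)
  check_scalar(amplitude_E, "amplitude_E", positive = TRUE)
  check_scalar(amplitude_R, "amplitude_R", positive = TRUE)
  structure(list(rate_E = rate_E, rate_R = rate_R,
                 amplitude_E = amplitude_E, amplitude_R = amplitude_R,
                 scheme = scheme),
            class = "pulse_spec")
}

#' Generate a stochastic pulse train
#'
#' Draws impulse times independently and uniformly on `[0, duration)`. Under
#' the default fixed-count scheme a realisation carries exactly
#' `round(rate_per_year * duration / 365)` impulses, so the nominal frequency
#' is preserved across seeds; only the timing changes with the seed.
#'
#' @param rate_per_year impulses per year, >= 0.
#' @param amplitude cells added per impulse, > 0.
#' @param duration train span, days, >= 0.
#' @param seed integer seed for the train's own random stream.
#' @param scheme `"fixed"` or `"poisson"` impulse count (see [pulse_spec()]).
#' @return an object of class `pulse_train`: list with `times` (sorted,
#'   days), `amplitude`, `duration`, `seed`.
#' @examples
#' tr <- generate_pulse_train(100, 1000, 365, seed = 1)
#' length(tr$times) # exactly 100
#' @export
generate_pulse_train <- function(rate_per_year, amplitude, duration, seed,
                                 scheme = c("fixed", "poisson")) {
  scheme <- match.arg(scheme)
  check_scalar(rate_per_year, "rate_per_year", nonneg = TRUE)
  check_scalar(duration, "duration", nonneg = TRUE)
  check_scalar(amplitude, "amplitude", positive = TRUE)
  mean_n <- rate_per_year * duration / 365
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- if (scheme == "fixed") round(mean_n) else rpois(1, mean_n)
  times <- if (n > 0) sort(runif(n, 0, duration)) else numeric(0)
  structure(list(times = times, amplitude = amplitude,
                 duration = duration, seed = as.integer(seed)),
            class = "pulse_train")
}

# Save/restore the global RNG state so train generation is a self-contained
# stream and does not disturb the caller's RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Expected (mean) inflow of a pulse train
#'
#' The constant influx used by the reduced deterministic model:
#' `Lambda = rate_per_year * amplitude / 365` cells/day, the expected value
#' of the stochastic forcing.
#'
#' @param spec a [pulse_spec()].
#' @return named numeric `c(lambda_E = , lambda_R = )`, cells/day.
#' @examples
#' expected_inflow(pulse_spec(rate_E = 100, amplitude_E = 365))["lambda_E"]
#' @export
expected_inflow <- function(spec = pulse_spec()) {
  c(lambda_E = spec$rate_E * spec$amplitude_E / 365,
    lambda_R = spec$rate_R * spec$amplitude_R / 365)
}

#' Write / read a pulse train as a two-column delimited table
#'
#' Columns `time_days` and `amplitude_cells`; tab-separated. Enables exact
#' replay of a forcing realisation.
#'
#' @param train a [generate_pulse_train()] result.
#' @param path file path.
#' @return `read_pulse_train` returns a `pulse_train` (with `seed = NA`).
#' @export
write_pulse_train <- function(train, path) {
  df <- data.frame(time_days = train$times,
                   amplitude_cells = rep(train$amplitude,
                                         length(train$times)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pulse_train
#' @param duration span of the replayed train, days; defaults to the latest
#'   impulse time rounded up.
#' @export
read_pulse_train <- function(path, duration = NULL) {
  df <- read.delim(path)
  if (!all(c("time_days", "amplitude_cells") %in% names(df)))
    stop_domain("pulse train table needs columns time_days, amplitude_cells")
  o <- order(df$time_days)
  amp <- unique(df$amplitude_cells)
  structure(list(times = df$time_days[o],
                 amplitude = if (length(amp) == 1) amp else df$amplitude_cells[o],
                 duration = duration %||%
                   (if (nrow(df)) ceiling(max(df$time_days)) else 0),
                 seed = NA_integer_),
            class = "pulse_train")
}
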