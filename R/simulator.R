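#' Simulation configuration
#'
#' Bundles parameters, initial state, time grid, forcing spec and master
#' seed. Defaults follow the reference setup of the model: a 1,825-day
#' (5-year) run on a fixed grid of 0.05 days, started from 0 resting cells,
#' 1,000 activated Teff, 200 activated Treg and no damage.
#'
#' @param params a [model_parameters()] object.
#' @param damage_params a [damage_parameters()] object.
#' @param initial_state named numeric `(E_r, R_r, E, R, l, L)`.
#' @param duration run length, days.
#' @param dt integration step, days.
#' @param master_seed integer; seeds for the two pulse trains are derived
#'   from it with [derive_seed()].
#' @param pulse a [pulse_spec()].
#' @param record_stride integer; record every `record_stride`-th step
#'   (1 = every step).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(params = model_parameters(),
                       damage_params = damage_parameters(),
                       initial_state = c(E_r = 0, R_r = 0, E = 1000, R = 200,
                                         l = 0, L = 0),
                       duration = 1825, dt = 0.05, master_seed = 1,
                       pulse = pulse_spec(), record_stride = 1L) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  if (duration < dt) stop_domain("duration must be >= dt")
  if (length(initial_state) != 6 || any(initial_state < 0))
    stop_domain("initial_state must be six non-negative components")
  names(initial_state) <- c("E_r", "R_r", "E", "R", "l", "L")
  structure(list(params = params, damage_params = damage_params,
                 initial_state = initial_state, duration = duration,
                 dt = dt, master_seed = as.integer(master_seed),
                 pulse = pulse, record_stride = as.integer(record_stride)),
            class = "sim_config")
}

#' Regime presets
#'
#' `healthy_config()` uses the homeostatic loop strength (alpha_E = 2,
#' alpha_R = 1); `autoimmune_config()` differs only in the weakened Treg
#' proliferation rate alpha_R = 0.25, which is what turns homeostatic
#' fluctuation into relapsing bursts.
#'
#' @param ... passed to [sim_config()] (e.g. `master_seed`, `duration`).
#' @return a `sim_config`.
#' @export
healthy_config <- function(...) {
  sim_config(params = model_parameters(alpha_E = 2, alpha_R = 1), ...)
}

#' @rdname healthy_config
#' @export
autoimmune_config <- function(...) {
  sim_config(params = model_parameters(alpha_E = 2, alpha_R = 0.25), ...)
}

# Map impulse times to 0-based grid indices: an impulse at time t is applied
# at the first grid point >= t (delta function realised as a state jump).
impulse_steps <- function(times, dt) as.integer(ceiling(times / dt - 1e-9))

#' Simulate the full six-variable system
#'
#' Explicit fixed-step Euler integration of the T-cell and damage equations
#' under pulse-train forcing. Impulses are applied as instantaneous state
#' jumps at the first grid point at or after their drawn time; any component
#' pushed below zero by a step is clipped to exactly zero and the event
#' counted. The run is fully deterministic given the configuration
#' (including `master_seed`).
#'
#' @param config a [sim_config()].
#' @param trains optional list with elements `E` and `R`, each a
#'   [generate_pulse_train()] result, to replay a fixed forcing realisation
#'   (used for common-random-number comparisons). When `NULL`, trains are
#'   generated from `config$master_seed` (streams 1 and 2).
#' @param extra_impulses optional data frame with columns `time` (days),
#'   `population` (one of `"resting_E"`, `"resting_R"`, `"active_E"`,
#'   `"active_R"`) and `amount` (cells) -- scheduled perturbations such as
#'   cell therapy doses.
#' @param constant_inflow named numeric `c(i_E = , i_R = )`, cells/day, added
#'   as a continuous influx into the resting pools (zero by default; used to
#'   match the reduced model's expected forcing).
#' @return an object of class `relapse_trajectory`: list with `times`,
#'   `states` (data frame `time, E_r, R_r, E, R, l, L`), `config`, `events`
#'   (applied trains, clip count, cells injected) and scalar summaries
#'   `peak_E`, `peak_R`, `mean_l`.
#' @examples
#' traj <- simulate_model(healthy_config(duration = 30, master_seed = 3))
#' max(traj$states$E)
#' @export
simulate_model <- function(config, trains = NULL, extra_impulses = NULL,
                           constant_inflow = c(i_E = 0, i_R = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(trains)) {
    trains <- list(
      E = generate_pulse_train(config$pulse$rate_E, config$pulse$amplitude_E,
                               config$duration,
                               derive_seed(config$master_seed, 1),
                               config$pulse$scheme),
      R = generate_pulse_train(config$pulse$rate_R, config$pulse$amplitude_R,
                               config$duration,
                               derive_seed(config$master_seed, 2),
                               config$pulse$scheme))
  }
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))

  pool_code <- c(resting_E = 0L, resting_R = 1L, active_E = 2L, active_R = 3L)
  step <- c(impulse_steps(trains$E$times, dt),
            impulse_steps(trains$R$times, dt))
  pool <- c(rep(0L, length(trains$E$times)), rep(1L, length(trains$R$times)))
  amount <- c(rep_len(trains$E$amplitude, length(trains$E$times)),
              rep_len(trains$R$amplitude, length(trains$R$times)))
  if (!is.null(extra_impulses) && nrow(extra_impulses)) {
    if (!all(extra_impulses$population %in% names(pool_code)))
      stop_domain("unknown population label in extra_impulses")
    step <- c(step, impulse_steps(extra_impulses$time, dt))
    pool <- c(pool, pool_code[extra_impulses$population])
    amount <- c(amount, extra_impulses$amount)
  }
  o <- order(step)
  res <- euler_core(unname(config$initial_state),
                    core_pars(config$params, config$damage_params,
                              constant_inflow[["i_E"]],
                              constant_inflow[["i_R"]]),
                    step[o], pool[o], amount[o],
                    n_steps, dt, config$record_stride)
  rec <- res$record
  states <- data.frame(time = rec[, 1], E_r = rec[, 2], R_r = rec[, 3],
                       E = rec[, 4], R = rec[, 5], l = rec[, 6], L = rec[, 7])
  structure(list(times = states$time, states = states, config = config,
                 events = list(train_E = trains$E, train_R = trains$R,
                               extra_impulses = extra_impulses,
                               n_clips = res$n_clips,
                               injected = res$injected,
                               n_impulses_applied = res$n_impulses_applied),
                 peak_E = res$peak_E, peak_R = res$peak_R,
                 mean_l = res$mean_l, final_state = res$final_state),
            class = "relapse_trajectory")
}

#' @export
print.relapse_trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %g days (dt = %g), %d samples; peak E = %.3g cells, final L = %.3g\n",
    x$config$duration, x$config$dt, nrow(x$states), x$peak_E,
    x$final_state[6]))
  invisible(x)
}

#' Apply an instantaneous cell impulse to a state
#'
#' Adds `magnitude` cells to one named pool, leaving the others unchanged --
#' equivalent to restarting the model from modified initial conditions.
#'
#' @param state named numeric state vector containing the pool.
#' @param population `"resting_E"`, `"resting_R"`, `"active_E"` or
#'   `"active_R"`.
#' @param magnitude cells to add, >= 0.
#' @return the updated state vector.
#' @export
apply_impulse <- function(state,
                          population = c("active_R", "active_E",
                                         "resting_E", "resting_R"),
                          magnitude) {
  population <- match.arg(population)
  check_scalar(magnitude, "magnitude", nonneg = TRUE)
  key <- c(resting_E = "E_r", resting_R = "R_r",
           active_E = "E", active_R = "R")[[population]]
  if (!key %in% names(state)) stop_domain("state lacks component ", key)
  state[[key]] <- state[[key]] + magnitude
  state
}

#' Detect relapse episodes on a trajectory
#'
#' A relapse is operationalised as a maximal interval during which activated
#' Teff stays at or above a population threshold (default: the damage
#' threshold `a` = 22,800 cells, the only population-scale threshold the
#' model provides).
#'
#' @param traj a `relapse_trajectory`.
#' @param threshold cells, > 0.
#' @return a data frame with one row per episode: `start`, `peak_time`,
#'   `peak_E`, `end` (days); zero rows when the threshold is never crossed.
#' @export
detect_relapses <- function(traj, threshold = damage_parameters()$a) {
  check_scalar(threshold, "threshold", positive = TRUE)
  E <- traj$states$E
  t <- traj$states$time
  above <- E >= threshold
  if (!any(above)) {
    return(data.frame(start = numeric(0), peak_time = numeric(0),
                      peak_E = numeric(0), end = numeric(0)))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  out <- lapply(idx, function(i) {
    seg <- starts[i]:ends[i]
    pk <- seg[which.max(E[seg])]
    data.frame(start = t[starts[i]], peak_time = t[pk], peak_E = E[pk],
               end = t[ends[i]])
  })
  do.call(rbind, out)
}

#' Export / import a trajectory as a tidy delimited table
#'
#' Writes `time, E_r, R_r, E, R, l, L` as a tab-separated table, and a JSON
#' run manifest (configuration, seed, package version) alongside when
#' `manifest = TRUE`.
#'
#' @param traj a `relapse_trajectory`.
#' @param path output table path.
#' @param manifest write `<path>.manifest.json`?
#' @return `read_trajectory` returns a data frame of states (the manifest,
#'   if present, is attached as attribute `"manifest"`).
#' @export
write_trajectory <- function(traj, path, manifest = TRUE) {
  write.table(traj$states, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (manifest) {
    cfg <- traj$config
    man <- list(command = "simulate", duration = cfg$duration, dt = cfg$dt,
                master_seed = cfg$master_seed,
                params = unclass(cfg$params),
                damage_params = unclass(cfg$damage_params),
                initial_state = as.list(cfg$initial_state),
                pulse = unclass(cfg$pulse),
                record_stride = cfg$record_stride,
                package_version = as.character(packageVersion("relapsim")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                output = basename(path))
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.delim(path)
  mpath <- paste0(path, ".manifest.json")
  if (file.exists(mpath))
    attr(df, "manifest") <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  df
}
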