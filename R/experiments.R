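#' Sensitivity sweep over the proliferation-rate plane
#'
#' Full-factorial scan of the maximum Teff and Treg proliferation rates.
#' Each grid cell is simulated for `n_seeds` independent noise realisations
#' (seeds derived from `master_seed` and the cell coordinates, so cells are
#' order-insensitive) and the maximum activated-Teff value of each run is
#' retained. At full scale the reference grid is `alpha_E` in `[1, 2]` and
#' `alpha_R` in `[0.25, 1]` in steps of 0.05 (21 x 16 cells) with 200 seeds
#' per cell; the defaults here are that grid, and smaller grids are obtained
#' by passing shorter vectors.
#'
#' @param alpha_E_grid,alpha_R_grid numeric grids of proliferation rates.
#' @param n_seeds realisations per cell, >= 1.
#' @param duration days per simulation.
#' @param master_seed integer.
#' @param base_config template `sim_config` supplying every other setting.
#' @return an object of class `sweep_result`: list with `peaks` (long data
#'   frame `alpha_E, alpha_R, seed_index, seed, peak_E`), `summary` (per-cell
#'   `median_peak`, `mean_peak`), the grids and `n_seeds`.
#' @export
sensitivity_sweep <- function(alpha_E_grid = seq(1, 2, by = 0.05),
                              alpha_R_grid = seq(0.25, 1, by = 0.05),
                              n_seeds = 200, duration = 1825,
                              master_seed = 1,
                              base_config = autoimmune_config()) {
  if (n_seeds < 1) stop_domain("n_seeds must be >= 1")
  rows <- vector("list", length(alpha_E_grid) * length(alpha_R_grid))
  idx <- 0L
  for (i in seq_along(alpha_E_grid)) {
    for (j in seq_along(alpha_R_grid)) {
      pk <- numeric(n_seeds)
      sds <- integer(n_seeds)
      for (rep in seq_len(n_seeds)) {
        sds[rep] <- derive_seed(master_seed, i, j, rep)
        cfg <- base_config
        cfg$params$alpha_E <- alpha_E_grid[i]
        cfg$params$alpha_R <- alpha_R_grid[j]
        cfg$duration <- duration
        cfg$master_seed <- sds[rep]
        cfg$record_stride <- 0L # summary only
        traj <- tryCatch(simulate_model(cfg), error = function(e) {
          stop_domain(sprintf("simulation failed at alpha_E=%g, alpha_R=%g, replicate %d: %s",
                              alpha_E_grid[i], alpha_R_grid[j], rep,
                              conditionMessage(e)))
        })
        pk[rep] <- traj$peak_E
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(alpha_E = alpha_E_grid[i],
                                alpha_R = alpha_R_grid[j],
                                seed_index = seq_len(n_seeds), seed = sds,
                                peak_E = pk)
    }
  }
  peaks <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(
    peaks, list(peaks$alpha_E, peaks$alpha_R), drop = TRUE),
    function(d) data.frame(alpha_E = d$alpha_E[1], alpha_R = d$alpha_R[1],
                           median_peak = median(d$peak_E),
                           mean_peak = mean(d$peak_E))))
  rownames(summary) <- NULL
  structure(list(peaks = peaks, summary = summary,
                 alpha_E_grid = alpha_E_grid, alpha_R_grid = alpha_R_grid,
                 n_seeds = n_seeds, master_seed = master_seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sensitivity sweep: %d x %d grid, %d seeds per cell\n",
              length(x$alpha_E_grid), length(x$alpha_R_grid), x$n_seeds))
  print(head(x$summary))
  invisible(x)
}

#' Write a sweep result as a long-format table plus JSON summary
#'
#' @param sweep a `sweep_result`.
#' @param path table path (tab-separated); the JSON summary is written to
#'   `<path>.summary.json`.
#' @export
write_sweep <- function(sweep, path) {
  write.table(sweep$peaks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(alpha_E_grid = sweep$alpha_E_grid,
         alpha_R_grid = sweep$alpha_R_grid,
         n_seeds = sweep$n_seeds, master_seed = sweep$master_seed,
         summary = sweep$summary),
    paste0(path, ".summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Seed-convergence check of a running statistic
#'
#' Declares a stream of running values (e.g. the running mean of per-seed
#' peaks over an increasing number of realisations) converged when, over a
#' trailing window, the spread `max - min` of the stream falls below `tol`.
#' Because peak sizes span orders of magnitude, the spread is measured
#' relative to the current value by default.
#'
#' @param stream numeric vector of running statistic values.
#' @param tol convergence tolerance (default 1e-5).
#' @param window trailing window length in seeds (default 50).
#' @param relative divide the spread by `abs(stream[n])`?
#' @return list with `converged` (flag) and `n_at_convergence` (first stream
#'   index at which the criterion holds; `NA` if never).
#' @export
convergence_check <- function(stream, tol = 1e-5, window = 50,
                              relative = TRUE) {
  if (length(stream) == 0) stop_domain("empty statistic stream")
  n <- length(stream)
  if (n >= window) {
    for (i in window:n) {
      w <- stream[(i - window + 1):i]
      spread <- max(w) - min(w)
      if (relative) spread <- spread / max(abs(stream[i]), .Machine$double.xmin)
      if (spread < tol) return(list(converged = TRUE, n_at_convergence = i))
    }
  }
  list(converged = FALSE, n_at_convergence = NA_integer_)
}

#' Perturbation (immunotherapy) experiment
#'
#' Runs a regime preset, applies a single cell impulse according to a timing
#' rule, and compares the perturbed run with the unperturbed baseline under
#' common random numbers (both arms share the identical pulse-train
#' realisation, so every difference is attributable to the impulse).
#'
#' @param regime `"healthy"` or `"autoimmune"`.
#' @param population pool receiving the impulse: `"active_R"` (Treg therapy)
#'   or `"active_E"` (Teff therapy); resting pools also allowed.
#' @param magnitude cells, >= 0, or `NULL`: raise the pool to the maximum
#'   value it reaches on the unperturbed trajectory (a dose near the maximum
#'   feasible level of that population).
#' @param timing either `list(type = "time", day = <days>)` or
#'   `list(type = "sector", sector = "IV", after = <days>)`, the first entry
#'   of the baseline trajectory into the given phase-plane sector after the
#'   given day.
#' @param master_seed integer.
#' @param duration days.
#' @param ... passed to the preset constructor.
#' @return an object of class `therapy_outcome`: regime, population,
#'   magnitude, perturbation time and sector, pre/post maximum activated
#'   Teff, pre/post cumulative reversible damage (integral of `l` dt) and
#'   final irreversible damage for both arms, plus both trajectories.
#' @export
therapy_experiment <- function(regime = c("healthy", "autoimmune"),
                               population = "active_R", magnitude = NULL,
                               timing = list(type = "time", day = 200),
                               master_seed = 1, duration = 1825, ...) {
  regime <- match.arg(regime)
  cfg <- if (regime == "healthy") {
    healthy_config(master_seed = master_seed, duration = duration, ...)
  } else {
    autoimmune_config(master_seed = master_seed, duration = duration, ...)
  }
  trains <- list(
    E = generate_pulse_train(cfg$pulse$rate_E, cfg$pulse$amplitude_E,
                             duration, derive_seed(master_seed, 1),
                             cfg$pulse$scheme),
    R = generate_pulse_train(cfg$pulse$rate_R, cfg$pulse$amplitude_R,
                             duration, derive_seed(master_seed, 2),
                             cfg$pulse$scheme))
  baseline <- simulate_model(cfg, trains = trains)
  st <- baseline$states
  inflow <- expected_inflow(cfg$pulse)

  if (identical(timing$type, "time")) {
    t_pert <- timing$day
    if (t_pert < 0 || t_pert > duration)
      stop_domain("perturbation day outside the simulated span")
  } else if (identical(timing$type, "sector")) {
    lab <- sector_labels(st$E, st$R, cfg$params, inflow)
    ok <- which(lab == timing$sector & st$time > (timing$after %||% 0))
    if (!length(ok))
      stop_domain("timing rule never satisfied: no entry into sector ",
                  timing$sector, " after day ", timing$after %||% 0)
    t_pert <- st$time[ok[1]]
  } else stop_domain("unknown timing rule type")

  i_pert <- which.min(abs(st$time - t_pert))
  key <- c(resting_E = "E_r", resting_R = "R_r",
           active_E = "E", active_R = "R")[[population]]
  if (is.null(magnitude)) {
    magnitude <- max(0, max(st[[key]]) - st[[key]][i_pert])
  }
  check_scalar(magnitude, "magnitude", nonneg = TRUE)
  sector_at <- tryCatch(
    classify_sector(st$E[i_pert], st$R[i_pert], cfg$params, inflow),
    error = function(e) NA_character_)

  perturbed <- simulate_model(
    cfg, trains = trains,
    extra_impulses = data.frame(time = t_pert, population = population,
                                amount = magnitude))
  dt_rec <- cfg$dt * max(cfg$record_stride, 1L)
  pre <- st$time <= t_pert
  post <- st$time > t_pert
  stp <- perturbed$states
  structure(list(
    regime = regime, population = population, magnitude = magnitude,
    time = t_pert, sector = sector_at,
    pre_max_E = max(st$E[pre]),
    post_max_E_baseline = if (any(post)) max(st$E[post]) else NA_real_,
    post_max_E = if (any(post)) max(stp$E[post]) else NA_real_,
    pre_cum_l = sum(st$l[pre]) * dt_rec,
    post_cum_l_baseline = sum(st$l[post]) * dt_rec,
    post_cum_l = sum(stp$l[post]) * dt_rec,
    final_L_baseline = st$L[nrow(st)],
    final_L = stp$L[nrow(stp)],
    baseline = baseline, perturbed = perturbed),
    class = "therapy_outcome")
}

#' @export
print.therapy_outcome <- function(x, ...) {
  cat(sprintf(
    "Therapy experiment (%s regime): +%.3g cells to %s at day %.1f (sector %s)\n",
    x$regime, x$magnitude, x$population, x$time, x$sector))
  cat(sprintf("  max activated Teff: pre %.3g | post baseline %.3g | post perturbed %.3g\n",
              x$pre_max_E, x$post_max_E_baseline, x$post_max_E))
  cat(sprintf("  final irreversible damage: baseline %.3g | perturbed %.3g\n",
              x$final_L_baseline, x$final_L))
  invisible(x)
}

#' Serialise a therapy outcome to JSON
#'
#' @param outcome a `therapy_outcome`.
#' @param path output path.
#' @export
write_therapy_outcome <- function(outcome, path) {
  keep <- setdiff(names(outcome), c("baseline", "perturbed"))
  jsonlite::write_json(outcome[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
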