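#' Month length used for discretisation
#'
#' 365/12 days, so that a 120-month comparison window corresponds to 3,650
#' days (10 years). Configurable to 30-day months wherever it is consumed.
#' @export
MONTH_DAYS <- 365 / 12

#' Read a patient CEL table
#'
#' Reads a delimited table of monthly contrast-enhancing-lesion (CEL) counts
#' with header columns `patient_id`, `month`, `cel` and optional `edss`,
#' `relapse`. Months must be complete and consecutive per patient, counts
#' non-negative integers.
#'
#' @param path file path; tab-, comma- or semicolon-separated (sniffed from
#'   the header line).
#' @return a list of `patient_series` objects: `patient_id`, `cel` (integer
#'   vector), `edss`, `relapse` (or `NULL`), `source`.
#' @examples
#' path <- system.file("extdata", "synthetic_cel_example.tsv",
#'                     package = "relapsim")
#' cohort <- read_cel_table(path)
#' cohort[[1]]
#' @export
read_cel_table <- function(path) {
  hdr <- readLines(path, n = 1)
  sep <- if (grepl("\t", hdr)) "\t" else if (grepl(";", hdr)) ";" else ","
  df <- read.delim(path, sep = sep)
  need <- c("patient_id", "month", "cel")
  if (!all(need %in% names(df)))
    stop_domain("CEL table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$patient_id), function(d) {
    d <- d[order(d$month), ]
    rows <- rownames(d)
    if (any(!is.finite(d$cel) | d$cel < 0))
      stop_domain("negative or missing CEL count at row ", rows[
        which(!is.finite(d$cel) | d$cel < 0)[1]], " (patient ",
        d$patient_id[1], ")")
    if (any(abs(d$cel - round(d$cel)) > 1e-9))
      stop_domain("non-integer CEL count at row ",
                  rows[which(abs(d$cel - round(d$cel)) > 1e-9)[1]],
                  " (patient ", d$patient_id[1], ")")
    if (nrow(d) < 2) stop_domain("patient ", d$patient_id[1],
                                 " has fewer than 2 months")
    if (!all(diff(d$month) == 1))
      stop_domain("missing or duplicated month for patient ", d$patient_id[1],
                  " near month ", d$month[which(diff(d$month) != 1)[1]])
    patient_series(d$patient_id[1], as.integer(round(d$cel)),
                   edss = if ("edss" %in% names(d)) d$edss else NULL,
                   relapse = if ("relapse" %in% names(d))
                     as.logical(d$relapse) else NULL,
                   source = "real")
  })
  unname(out)
}

#' Patient series constructor
#'
#' @param patient_id label.
#' @param cel monthly CEL counts, non-negative integers, length >= 2.
#' @param edss optional monthly disability scores (pass-through only).
#' @param relapse optional monthly relapse flags (logical).
#' @param source `"real"` or `"synthetic"`.
#' @return an object of class `patient_series`.
#' @export
patient_series <- function(patient_id, cel, edss = NULL, relapse = NULL,
                           source = c("real", "synthetic")) {
  source <- match.arg(source)
  if (length(cel) < 2) stop_domain("cel length must be >= 2")
  if (any(!is.finite(cel) | cel < 0 | abs(cel - round(cel)) > 1e-9))
    stop_domain("cel must be non-negative integers")
  structure(list(patient_id = as.character(patient_id),
                 cel = as.integer(round(cel)), edss = edss,
                 relapse = relapse, source = source),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("Patient %s (%s): %d months, mean CEL %.2f\n",
              x$patient_id, x$source, length(x$cel), mean(x$cel)))
  invisible(x)
}

#' Write a cohort to the CEL table format
#'
#' Writes the same tab-separated format [read_cel_table()] consumes.
#'
#' @param cohort list of `patient_series`.
#' @param path output path.
#' @export
write_cel_table <- function(cohort, path) {
  rows <- lapply(cohort, function(p) {
    d <- data.frame(patient_id = p$patient_id,
                    month = seq_along(p$cel), cel = p$cel)
    if (!is.null(p$edss)) d$edss <- p$edss
    if (!is.null(p$relapse)) d$relapse <- as.integer(p$relapse)
    d
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Monthly discretisation of a trajectory variable
#'
#' Takes one instantaneous sample per month (the recorded state at the last
#' grid point at or before each month boundary), matching the temporal
#' resolution of monthly MRI.
#'
#' @param traj a `relapse_trajectory`.
#' @param variable column of the state table to sample (default `"l"`,
#'   reversible damage -- the model quantity compared with CEL counts).
#' @param months number of months; default all complete months,
#'   `floor(duration / month_days)`.
#' @param month_days days per month (default [MONTH_DAYS]).
#' @param mode `"sample"` (instantaneous value at the boundary) or `"mean"`
#'   (average over the month).
#' @return numeric vector of length `months`.
#' @export
monthly_series <- function(traj, variable = "l", months = NULL,
                           month_days = MONTH_DAYS,
                           mode = c("sample", "mean")) {
  mode <- match.arg(mode)
  total <- floor(traj$config$duration / month_days + 1e-9)
  months <- months %||% total
  if (months > total)
    stop_domain("trajectory too short: ", months, " months requested, ",
                total, " available")
  x <- traj$states[[variable]]
  t <- traj$states$time
  if (mode == "sample") {
    idx <- findInterval((1:months) * month_days + 1e-9, t)
    x[idx]
  } else {
    bin <- ceiling((t - 1e-9) / month_days)
    bin[bin < 1] <- 1
    as.numeric(tapply(x[bin <= months], bin[bin <= months], mean))
  }
}

#' First-differenced ("evolution") series
#'
#' `out[t] = s[t] - s[t-1]`: zero when activity is unchanged, positive on
#' exacerbation, negative on improvement. Applied to both the clinical CEL
#' series ("disease evolution") and the simulated reversible damage
#' ("in-silico evolution") before correlation.
#'
#' @param s numeric series, length >= 2.
#' @return numeric vector of length `length(s) - 1`.
#' @export
evolution_series <- function(s) {
  if (length(s) < 2) stop_domain("series must have length >= 2")
  diff(as.numeric(s))
}

#' Best sliding-window Pearson correlation
#'
#' Slides the shorter (disease) series along the longer (in-silico) series
#' and computes the Pearson correlation at every alignment offset
#' `0 .. n - m`; `n - m + 1` alignments in total. Returns the maximum
#' correlation and its offset (ties broken by the smallest offset).
#' Alignments where the simulated window has zero variance are skipped and
#' counted.
#'
#' @param disease numeric vector (length `m` >= 3) with nonzero variance.
#' @param insilico numeric vector (length `n` >= `m`).
#' @return list with `best_r`, `offset` (0-based), `n_alignments`,
#'   `n_skipped`, and `r` (per-offset correlations, `NA` where skipped).
#' @export
best_sliding_correlation <- function(disease, insilico) {
  m <- length(disease); n <- length(insilico)
  if (m < 3) stop_domain("disease series must have length >= 3")
  if (n < m) stop_domain("in-silico series shorter than disease series")
  if (sd(disease) == 0)
    stop_domain("undefined correlation: disease series has zero variance")
  offs <- 0:(n - m)
  r <- vapply(offs, function(o) {
    w <- insilico[(o + 1):(o + m)]
    if (sd(w) == 0) NA_real_ else cor(disease, w)
  }, numeric(1))
  if (all(is.na(r)))
    stop_domain("every simulated window has zero variance")
  best <- which.max(r) # first maximum -> smallest offset on ties
  list(best_r = r[best], offset = offs[best],
       n_alignments = length(offs), n_skipped = sum(is.na(r)), r = r)
}

#' Bank of in-silico evolution series
#'
#' Simulates `n_simulations` independent autoimmune runs, discretises the
#' reversible damage monthly and first-differences each series. One bank can
#' be shared across all patients of a cohort.
#'
#' @param n_simulations count.
#' @param config template `sim_config` (its duration is set from `months`).
#' @param months window length in months (default 120).
#' @param master_seed integer.
#' @param month_days days per month.
#' @return matrix with `months - 1` rows, one column per simulation;
#'   attribute `"seeds"` carries the per-simulation seeds.
#' @export
simulate_evolution_bank <- function(n_simulations,
                                    config = autoimmune_config(),
                                    months = 120, master_seed = 1,
                                    month_days = MONTH_DAYS) {
  if (n_simulations < 1) stop_domain("n_simulations must be >= 1")
  cfg <- config
  cfg$duration <- ceiling(months * month_days)
  cfg$record_stride <- max(1L, as.integer(floor(month_days / cfg$dt / 8)))
  seeds <- vapply(seq_len(n_simulations),
                  function(i) derive_seed(master_seed, 900, i), integer(1))
  bank <- matrix(NA_real_, nrow = months - 1, ncol = n_simulations)
  for (i in seq_len(n_simulations)) {
    cfg$master_seed <- seeds[i]
    traj <- simulate_model(cfg)
    bank[, i] <- evolution_series(
      monthly_series(traj, "l", months = months, month_days = month_days))
  }
  attr(bank, "seeds") <- seeds
  bank
}

#' Correlation distribution between a patient and simulated damage
#'
#' For each simulated series: autoimmune simulation -> monthly reversible
#' damage -> evolution series -> best sliding correlation against the
#' patient's evolution series. Collects the per-simulation best correlation
#' coefficients.
#'
#' @param patient a `patient_series`.
#' @param n_simulations simulations to compare against (reference scale:
#'   2,000); ignored when `bank` is supplied.
#' @param config template `sim_config` for the simulations (autoimmune).
#' @param months simulated window, months (default 120).
#' @param master_seed integer.
#' @param bank optional precomputed [simulate_evolution_bank()] shared
#'   across patients.
#' @return an object of class `correlation_distribution`: `patient_id`,
#'   `best_r` (one per simulation), `offset`, `n_excluded` (simulations whose
#'   comparison failed, e.g. all-zero windows), `median_r`, `max_r`,
#'   `mode_bin` (midpoint of the modal 0.05-wide histogram bin).
#' @export
correlation_distribution <- function(patient, n_simulations = 2000,
                                     config = autoimmune_config(),
                                     months = 120, master_seed = 1,
                                     bank = NULL) {
  stopifnot(inherits(patient, "patient_series"))
  if (is.null(bank))
    bank <- simulate_evolution_bank(n_simulations, config, months,
                                    master_seed)
  disease <- evolution_series(patient$cel)
  res <- apply(bank, 2, function(col) {
    tryCatch(unlist(best_sliding_correlation(disease, col)[c("best_r", "offset")]),
             error = function(e) c(best_r = NA_real_, offset = NA_real_))
  })
  best_r <- res["best_r", ]
  excl <- sum(is.na(best_r))
  keep <- best_r[!is.na(best_r)]
  if (length(keep)) {
    hh <- hist(pmin(pmax(keep, -1), 1), breaks = seq(-1, 1, by = 0.05),
               plot = FALSE)
    med <- median(keep); mx <- max(keep)
    mode_bin <- hh$mids[which.max(hh$counts)]
  } else {
    med <- mx <- mode_bin <- NA_real_
  }
  structure(list(patient_id = patient$patient_id, best_r = best_r,
                 offset = res["offset", ], n_simulations = ncol(bank),
                 n_excluded = excl,
                 median_r = med, max_r = mx, mode_bin = mode_bin),
            class = "correlation_distribution")
}

#' @export
print.correlation_distribution <- function(x, ...) {
  cat(sprintf(
    "Patient %s vs %d simulations: median best-r %.3f (mode bin %.3f, max %.3f, %d excluded)\n",
    x$patient_id, x$n_simulations, x$median_r, x$mode_bin, x$max_r,
    x$n_excluded))
  invisible(x)
}

#' @importFrom graphics hist
NULL
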