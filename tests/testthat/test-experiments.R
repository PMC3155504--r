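test_that("sweep bookkeeping: cells x seeds simulations, all peaks retained", {
  sw <- sensitivity_sweep(alpha_E_grid = c(1, 2), alpha_R_grid = c(0.25, 1),
                          n_seeds = 3, duration = 60, master_seed = 5)
  expect_equal(nrow(sw$peaks), 12)
  expect_true(all(sw$peaks$peak_E >= 0))
  expect_equal(nrow(sw$summary), 4)
  counts <- table(sw$peaks$alpha_E, sw$peaks$alpha_R)
  expect_true(all(counts == 3))
})

test_that("the reference grid dimensions are 21 x 16", {
  f <- formals(sensitivity_sweep)
  expect_length(eval(f$alpha_E_grid), 21)
  expect_length(eval(f$alpha_R_grid), 16)
  expect_equal(eval(f$n_seeds), 200)
})

test_that("sweeps are reproducible and order-insensitive in their seeds", {
  a <- sensitivity_sweep(c(1, 2), c(0.25, 1), n_seeds = 2, duration = 60,
                         master_seed = 9)
  b <- sensitivity_sweep(c(1, 2), c(0.25, 1), n_seeds = 2, duration = 60,
                         master_seed = 9)
  expect_identical(a$peaks, b$peaks)
  # a cell's seeds depend only on its coordinates, not on the grid around it
  sub <- sensitivity_sweep(c(1), c(0.25), n_seeds = 2, duration = 60,
                           master_seed = 9)
  expect_equal(sub$peaks$peak_E,
               a$peaks$peak_E[a$peaks$alpha_E == 1 & a$peaks$alpha_R == 0.25])
})

test_that("median peaks grow when Treg proliferation weakens", {
  sw <- sensitivity_sweep(alpha_E_grid = c(1, 2),
                          alpha_R_grid = c(0.25, 1),
                          n_seeds = 10, duration = 1825, master_seed = 3)
  s <- sw$summary
  for (ae in c(1, 2)) {
    expect_gt(s$median_peak[s$alpha_E == ae & s$alpha_R == 0.25],
              s$median_peak[s$alpha_E == ae & s$alpha_R == 1])
  }
})

test_that("sweep results persist as a long table plus JSON summary", {
  sw <- sensitivity_sweep(c(1.5), c(0.5), n_seeds = 2, duration = 30,
                          master_seed = 2)
  path <- tempfile(fileext = ".tsv")
  write_sweep(sw, path)
  back <- read.delim(path)
  expect_equal(back$peak_E, sw$peaks$peak_E)
  js <- jsonlite::read_json(paste0(path, ".summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$n_seeds, 2)
})

test_that("convergence detector handles constant, oscillating and shrinking streams", {
  const <- convergence_check(rep(5, 100), tol = 1e-5, window = 50)
  expect_true(const$converged)
  expect_equal(const$n_at_convergence, 50)
  alt <- convergence_check(rep(c(1, -1), 100), tol = 1e-5, window = 50)
  expect_false(alt$converged)
  expect_true(is.na(alt$n_at_convergence))
  expect_error(convergence_check(numeric(0)), "empty")
})

test_that("running means converge sooner when the draw variance is smaller", {
  set.seed(12)
  run_mean <- function(sigma) cumsum(rnorm(4000, 1, sigma)) / seq_len(4000)
  lo <- convergence_check(run_mean(0.01), tol = 1e-3, window = 50)
  hi <- convergence_check(run_mean(0.5), tol = 1e-3, window = 50)
  expect_true(lo$converged)
  if (hi$converged) {
    expect_lt(lo$n_at_convergence, hi$n_at_convergence)
  }
})

test_that("a zero-magnitude therapy changes nothing", {
  out <- therapy_experiment("autoimmune", magnitude = 0,
                            timing = list(type = "time", day = 100),
                            master_seed = 2, duration = 400,
                            record_stride = 20L)
  expect_identical(out$baseline$states, out$perturbed$states)
  expect_equal(out$post_max_E, out$post_max_E_baseline)
})

test_that("therapy arms share the pre-perturbation trajectory exactly", {
  out <- therapy_experiment("autoimmune", magnitude = 5e3,
                            timing = list(type = "time", day = 150),
                            master_seed = 4, duration = 500,
                            record_stride = 20L)
  pre <- out$baseline$states$time < out$time
  expect_identical(out$baseline$states[pre, ], out$perturbed$states[pre, ])
  i <- sum(pre) + 1
  expect_equal(out$perturbed$states$R[i] - out$baseline$states$R[i], 5e3)
})

test_that("sector timing rules find a perturbation time or fail loudly", {
  out <- therapy_experiment("autoimmune",
                            timing = list(type = "sector", sector = "IV",
                                          after = 100),
                            master_seed = 1, duration = 600,
                            record_stride = 20L)
  expect_identical(out$sector, "IV")
  expect_gt(out$time, 100)
  expect_error(
    therapy_experiment("autoimmune",
                       timing = list(type = "sector", sector = "IV",
                                     after = 1e6),
                       master_seed = 1, duration = 300, record_stride = 20L),
    "timing rule never satisfied")
})

test_that("the same dose is far more consequential in the autoimmune regime", {
  mag <- 2000
  th <- therapy_experiment("healthy", magnitude = mag,
                           timing = list(type = "time", day = 200),
                           master_seed = 2, record_stride = 20L)
  ta <- therapy_experiment("autoimmune", magnitude = mag,
                           timing = list(type = "time", day = 200),
                           master_seed = 2, record_stride = 20L)
  expect_gt(ta$post_max_E, 10 * th$post_max_E)
  expect_gt(ta$final_L, 20 * th$final_L)
})

test_that("small Treg doses in sector I land on nearer spirals than large ones", {
  infl <- default_inflow()
  p <- model_parameters(alpha_R = 0.25)
  expect_identical(classify_sector(1350, 250, p, infl), "I")
  small <- max(phase_trajectory(p, infl, start = c(E = 1350, R = 250 + 30),
                                duration = 600)$E)
  large <- max(phase_trajectory(p, infl, start = c(E = 1350, R = 250 + 1000),
                                duration = 600)$E)
  expect_lt(small, large)
})

test_that("therapy outcomes serialise to JSON without the trajectories", {
  out <- therapy_experiment("healthy", magnitude = 10,
                            timing = list(type = "time", day = 50),
                            master_seed = 1, duration = 100,
                            record_stride = 20L)
  path <- tempfile(fileext = ".json")
  write_therapy_outcome(out, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$magnitude, 10)
  expect_null(js$baseline)
})
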