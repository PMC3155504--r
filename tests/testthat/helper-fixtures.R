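# Shared fixtures for the suite. Everything is generated in code; short
# horizons keep individual tests fast.

default_inflow <- function() expected_inflow(pulse_spec())

# a quiet pulse spec whose trains carry zero impulses (rate rounds to 0)
quiet_pulse <- function() pulse_spec(rate_E = 1e-3, rate_R = 1e-3)

constant_inflow_vec <- function() {
  infl <- default_inflow()
  c(i_E = unname(infl[["lambda_E"]]), i_R = unname(infl[["lambda_R"]]))
}

# minimal trajectory-shaped object for detector tests
fake_trajectory <- function(time, E) {
  structure(list(times = time,
                 states = data.frame(time = time, E_r = 0, R_r = 0, E = E,
                                     R = 0, l = 0, L = 0),
                 config = list(duration = max(time), dt = diff(time)[1])),
            class = "relapse_trajectory")
}

# two-patient CEL table fixture on disk; returns the path
write_cel_fixture <- function(path = tempfile(fileext = ".tsv"),
                              mangle = NULL) {
  df <- data.frame(
    patient_id = rep(c("P1", "P2"), each = 6),
    month = rep(1:6, 2),
    cel = c(0L, 2L, 1L, 0L, 4L, 1L, 3L, 0L, 0L, 1L, 2L, 5L),
    edss = rep(c(1.5, 2.0), each = 6),
    relapse = c(0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L))
  if (!is.null(mangle)) df <- mangle(df)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}
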