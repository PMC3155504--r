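#' Derive a reproducible child seed from a master seed
#'
#' Splittable counter scheme: child streams (pulse trains, sweep cells,
#' simulation banks, patients) get seeds that depend only on the master seed
#' and their own integer coordinates, so they are independent of evaluation
#' order. Uses a Lehmer-style mix modulo the Mersenne prime 2^31 - 1; all
#' intermediates stay below 2^53 so the arithmetic is exact in doubles.
#'
#' @param master integer master seed.
#' @param ... integer coordinates identifying the stream (e.g. cell row,
#'   column, replicate).
#' @return a positive integer seed below 2^31 - 1.
#' @export
derive_seed <- function(master, ...) {
  p <- 2147483647
  keys <- c(...)
  x <- (abs(as.numeric(master)) + 1) %% p
  x <- (x * 48271 + 11) %% p
  for (k in keys) {
    x <- (x * 48271 + abs(as.numeric(k)) + 1) %% p
    x <- (x * 69621 + 7) %% p
  }
  as.integer(x %% (p - 1) + 1)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_domain(name, " must be strictly positive")
  if (nonneg && x < 0) stop_domain(name, " must be non-negative")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
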