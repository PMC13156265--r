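# Internal helpers shared across modules.

# Classed errors/warnings so callers can distinguish failure modes.
rlr_error <- function(msg, class, call. = FALSE, ...) {
  stop(structure(
    class = c(paste0("ratlungref_error_", class), "ratlungref_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

rlr_warning <- function(msg, class) {
  warning(structure(
    class = c(paste0("ratlungref_warning_", class), "ratlungref_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Sample skewness (third standardized moment) and excess kurtosis, with the
# population (divisor n) convention.
sample_skewness <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  mean((x - m)^4) / s^4 - 3
}
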