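# Internal helpers shared across modules.

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is round-half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Quantize to a dB step grid (audiometer practice: 5 dB), half-up.
quantize_db <- function(x, step = 5) step * round_half_up(x / step)

# Number of decimals a printed value carries (2.5 -> 1, 6.76 -> 2, 100 -> 0).
printed_decimals <- function(x, max_digits = 6) {
  for (d in 0:max_digits) {
    if (abs(x - round_half_up(x, d)) < 1e-9) return(d)
  }
  max_digits
}

# Independent child seeds derived from one master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Truncated-normal draws by inverse-CDF (deterministic: one uniform each).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# djb2-style 31-bit hash of a deparsed object; used to stamp output files so
# a report can be traced back to the configuration that produced it.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
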