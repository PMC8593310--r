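#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble as_tibble tibble
#' @importFrom stats rnorm runif sd lm coef setNames
#' @importFrom utils head tail
NULL

# clamp a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# km/hr -> m/s
kmh_to_mps <- function(v) v * 1000 / 3600

# Derive a child seed from a master seed; kept below 2^31 so it is a valid
# R integer seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483587L)
}

check_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lo || x > hi || (strict_lo && x == lo)) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}
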