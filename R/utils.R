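#' Round a proportion to a reporting percentage
#'
#' Converts a proportion to the percentage convention used throughout the
#' package's concordance reporting: round half-up to the nearest integer,
#' except that a value whose exact percentage has a single decimal digit
#' (e.g. 5/8 = 62.5%) is reported with that one decimal.
#'
#' @param x proportion in \[0, 1\], or `NA`.
#' @return numeric percentage, or `NA` for undefined input.
#' @examples
#' roundPercent(22 / 26) # 85
#' roundPercent(5 / 8)   # 62.5
#' @export
roundPercent <- function(x) {
  if (is.na(x)) return(NA_real_)
  pct <- 100 * x
  one_dp <- round(pct, 1)
  if (abs(one_dp - pct) < 1e-9 && abs(one_dp - round(one_dp)) > 1e-9)
    return(one_dp)
  # round half up (round() would go half-even)
  floor(pct + 0.5)
}

# log(exp(a) + exp(b)) elementwise, tolerating -Inf in either argument
logSumExp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  both_inf <- is.infinite(m) & m < 0
  out[both_inf] <- -Inf
  out
}

# n * log(p) with the convention 0 * -Inf = 0
xlogy <- function(n, logp) {
  out <- n * logp
  out[n == 0] <- 0
  out
}

# clamp a probability away from the exact boundary for qlogis() starts
clampProb <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

# derive a stream-specific 32-bit seed from a master seed
deriveSeed <- function(seed, stream) {
  (as.integer(seed) + 7919L * as.integer(stream)) %% 2147483647L
}
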