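#' Round a ratio of integers half-away-from-zero
#'
#' Rule statistics and audit percentages are reported at fixed decimal
#' precision. Ordinary floating-point rounding can misplace values that sit
#' exactly on a rounding boundary, so ratios of integer counts are rounded
#' by exact integer arithmetic: `a/b` to `digits` decimals, ties away from
#' zero.
#'
#' @param a numerator (integer-valued, possibly negative).
#' @param b denominator (positive integer-valued).
#' @param digits number of decimal places.
#' @return `a/b` rounded half-away-from-zero to `digits` decimals.
#' @examples
#' round_ratio(669, 6168, 4)   # 0.1085
#' round_ratio(669, 687, 4)    # 0.9738
#' round_ratio(100 * 141, 828, 1) # 17.0
#' @export
round_ratio <- function(a, b, digits = 4L) {
  stopifnot(all(b > 0), all(a == trunc(a)), all(b == trunc(b)))
  s <- ifelse(a < 0, -1, 1)
  a <- abs(a)
  p <- 10^digits
  q <- (a * p) %/% b
  r <- (a * p) %% b
  q <- q + as.numeric(2 * r >= b)
  s * q / p
}

#' Round half-away-from-zero
#'
#' Used for display values that are not integer ratios (base R's `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# internal: stop with a classed condition so callers/tests can match errors
rx_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "rxminer_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
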