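#' Round half away from zero
#'
#' Display rounding used throughout the package.  Published CHNRI tables
#' round half-up (91.15 prints as 91.2), whereas base [round()] rounds half
#' to even; all internal arithmetic is carried at full precision and this
#' helper is applied only when values are rendered.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(91.15, 82.85), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a numeric column for display, keeping NA as "".
fmt_num <- function(x, digits) {
  out <- formatC(round_half_up(x, digits), format = "f", digits = digits)
  out[is.na(x)] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream of sub-seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}
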