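#' Round half-up
#'
#' Commercial ("half-up") rounding, used for reported percentages and
#' coefficients.  Base \code{round()} rounds half-to-even, which does not
#' reproduce conventional lab reporting (e.g. 70.4969 -> 70.50, 0.1165 -> 0.117).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up at \code{digits} decimals.
#' @examples
#' round_half_up(70.4969, 2)  # 70.50
#' round(70.4969 * 100) / 100 # banker's rounding differs
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Truncate to two decimals
#'
#' Floors a positive ratio at the second decimal place (no rounding).  A
#' tiny epsilon guards against values such as 1.00 being stored a binary
#' ulp below their decimal value.
#'
#' @param x numeric vector (non-negative).
#' @return numeric vector truncated at 2 decimals.
#' @keywords internal
trunc2 <- function(x) floor(x * 100 + 1e-9) / 100

# stop() with call. = FALSE everywhere; small wrapper keeps messages uniform
.fail <- function(...) stop(..., call. = FALSE)
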