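#' Round half to even at a given number of decimal digits
#'
#' Reported percentages in facility-readiness tables use banker's rounding
#' (round half to even), so 21.25 prints as 21.2 and 31.25 as 31.2. Base
#' [round()] follows the same convention but is sensitive to floating-point
#' representation of near-half values; this helper snaps values within a
#' relative machine tolerance of an exact half before deciding the direction.
#'
#' @param x numeric vector.
#' @param digits integer, decimal digits to keep (default 1).
#' @return numeric vector rounded half-to-even.
#' @export
#' @examples
#' round_half_even(100 * 34 / 160, 1)  # 21.2
#' round_half_even(100 * 45 / 246, 1)  # 18.3
round_half_even <- function(x, digits = 1) {
  s <- 10^digits
  y <- x * s
  f <- floor(y)
  r <- y - f
  eps <- sqrt(.Machine$double.eps) * pmax(1, abs(y))
  is_half <- abs(r - 0.5) <= eps
  out <- ifelse(is_half, f + (f %% 2), round(y))
  out / s
}

#' Format a count as a percentage of a total
#'
#' @param count numeric numerator.
#' @param n total.
#' @param digits decimal digits (default 1).
#' @return numeric percentage on the 0--100 scale, rounded half-to-even.
#' @export
pct_of <- function(count, n, digits = 1) {
  round_half_even(100 * count / n, digits)
}

# internal: stop with a classed condition so callers/tests can match on class
stop_cbready <- function(msg, class) {
  stop(structure(
    class = c(class, "cbready_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical response levels used throughout the package
response_levels <- function() {
  c("yes", "no", "dont_know", "missing", "not_applicable")
}

tier_levels <- function() c("hospital", "health_centre_clinic")
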