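#' Two-line (single change point) piecewise linear function
#'
#' Evaluates the continuous hinge parameterization of a two-line piecewise
#' linear dose-response: `b0 + b1 * x + b2 * (x - c)` for `x > c` and
#' `b0 + b1 * x` otherwise. The slope below the change point is `b1`; the
#' slope above is `b1 + b2`. The function is continuous at `x = c`.
#'
#' An inverted-U dose-response corresponds to `b1 > 0` and `b1 + b2 < 0`:
#' the response rises up to the change point and falls beyond it.
#'
#' @param x Numeric vector of exposure values (marker concentrations).
#' @param c Change point (breakpoint), in the units of `x`.
#' @param b0 Intercept.
#' @param b1 Slope below the change point.
#' @param b2 Change in slope at the change point (`slope_above - slope_below`).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' two_line(12, c = 10, b0 = 0, b1 = 1, b2 = -2)  # 12 - 2 * 2 = 8
#' @export
two_line <- function(x, c, b0, b1, b2) {
  b0 + b1 * x + b2 * pmax(x - c, 0)
}
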