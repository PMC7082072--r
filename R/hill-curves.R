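#' Hill saturation curves
#'
#' `hill_up()` is the increasing four-parameter Hill (sigmoidal) transition
#' `base + amplitude * y^n / (midpoint^n + y^n)`; `hill_down()` is its
#' decreasing mirror `base + amplitude * midpoint^n / (midpoint^n + y^n)`.
#' These are the transition shapes used throughout: for the synthetic
#' generator's expressing-fraction curves, for [fit_hill()], and for the
#' fate/expression regulation inside the simulator.
#'
#' @param y Position (or regulator abundance), non-negative numeric vector.
#' @param midpoint Position of half-maximal change (same units as `y`).
#' @param n Hill coefficient (> 0); larger is steeper.
#' @param base Offset added to the curve.
#' @param amplitude Total rise (or fall) of the curve.
#' @return Numeric vector, same length as `y`.
#' @examples
#' hill_up(c(0, 3000, 6000), midpoint = 3000, n = 30)
#' @export
hill_up <- function(y, midpoint, n, base = 0, amplitude = 1) {
  stopifnot(midpoint > 0, n > 0)
  r <- (y / midpoint)^n
  base + amplitude * r / (1 + r)
}

#' @rdname hill_up
#' @export
hill_down <- function(y, midpoint, n, base = 0, amplitude = 1) {
  stopifnot(midpoint > 0, n > 0)
  r <- (y / midpoint)^n
  base + amplitude / (1 + r)
}

# Analytic derivative of hill_up (increasing); for the decreasing form the
# derivative is the negation.
hill_up_deriv <- function(y, midpoint, n, amplitude = 1) {
  r <- (y / midpoint)^n
  out <- amplitude * n * r / (y * (1 + r)^2)
  out[y == 0] <- if (n > 1) 0 else NA_real_
  out
}
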