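#' Geman-McClure robust loss
#'
#' `rho(delta) = delta^2 / (1 + (delta/c)^2)`: quadratic for small
#' residuals, saturating at `c^2` for large ones, so restraints exhibiting
#' large differences exert vanishing force during refinement instead of
#' dragging the model toward an outlying target.
#'
#' @param delta residual(s), Angstrom (vectorized)
#' @param c scale parameter, Angstrom (> 0); residuals near `c` mark the
#'   transition from quadratic to saturated behaviour
#' @return list with `value` and `deriv` (d rho / d delta)
#' @export
geman_mcclure <- function(delta, c = 1) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0)
    stop("Geman-McClure scale c must be a positive number")
  u2 <- (delta / c)^2
  den <- 1 + u2
  list(value = delta^2 / den, deriv = 2 * delta / den^2)
}
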