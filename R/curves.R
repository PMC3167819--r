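#' Saturating regulatory curve
#'
#' All regulatory dependencies of the intracellular model are monotone
#' saturating functions of a single non-negative input, parameterised as Hill
#' curves. An `"up"` curve is zero at zero input, strictly increasing, and
#' saturates at `vmax`; a `"down"` curve equals `vmax` at zero input, is
#' strictly decreasing, and decays to zero. Both kinds pass through
#' `vmax / 2` at `half_sat`.
#'
#' @param kind `"up"` (activation) or `"down"` (inhibition).
#' @param vmax Asymptotic (kind `"up"`) or basal (kind `"down"`) value, in
#'   rate or dimensionless units depending on the role of the curve.
#' @param half_sat Input level at which the curve reaches `vmax / 2`.
#' @param hill Hill exponent (`>= 1`); steeper curves switch more sharply.
#' @return An object of class `reg_curve`.
#' @examples
#' up <- reg_curve("up", vmax = 1, half_sat = 0.5)
#' regulatory(0.5, up)  # vmax / 2
#' @seealso [regulatory()]
#' @export
reg_curve <- function(kind = c("up", "down"), vmax, half_sat, hill = 2) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(vmax), length(vmax) == 1L, vmax > 0,
            is.numeric(half_sat), length(half_sat) == 1L, half_sat > 0,
            is.numeric(hill), length(hill) == 1L, hill >= 1)
  structure(list(kind = kind, vmax = vmax, half_sat = half_sat, hill = hill),
            class = "reg_curve")
}

#' @export
print.reg_curve <- function(x, ...) {
  cat(sprintf("<reg_curve %s> vmax = %g, half_sat = %g, hill = %g\n",
              x$kind, x$vmax, x$half_sat, x$hill))
  invisible(x)
}

#' Evaluate a regulatory curve
#'
#' Computes `vmax * x^n / (K^n + x^n)` for an up curve and
#' `vmax * K^n / (K^n + x^n)` for a down curve, where `K` is the
#' half-saturation level and `n` the Hill exponent.
#'
#' @param value Non-negative input level(s).
#' @param curve A [reg_curve()].
#' @return Numeric vector of the same length as `value`.
#' @export
regulatory <- function(value, curve) {
  stopifnot(inherits(curve, "reg_curve"))
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("regulatory curve input must be finite and non-negative")
  }
  kn <- curve$half_sat^curve$hill
  xn <- value^curve$hill
  if (curve$kind == "up") curve$vmax * xn / (kn + xn) else curve$vmax * kn / (kn + xn)
}
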