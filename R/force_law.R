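#' Toe-then-linear force-displacement law
#'
#' The synthetic constitutive model: `F(x) = k (x - xt (1 - exp(-x/xt)))`,
#' an exponential toe region of extent `xt` blending smoothly into a linear
#' region of stiffness `k`. `F(0) = 0`, `F'(0) = 0`, and `F'(x) -> k` for
#' `x >> xt`. With `xt = 0` the law is exactly linear.
#'
#' @param x Displacement, mm (vectorized).
#' @param stiffness Linear-region stiffness `k`, N/mm.
#' @param toe_displacement Toe extent `xt`, mm (>= 0).
#' @return Force in N.
#' @export
force_law <- function(x, stiffness, toe_displacement) {
  if (toe_displacement <= 0) return(stiffness * x)
  stiffness * (x - toe_displacement * (1 - exp(-x / toe_displacement)))
}

#' Invert the toe-then-linear law
#'
#' Displacement at which [force_law()] reaches a given force.
#'
#' @param force Target force, N (>= 0).
#' @inheritParams force_law
#' @return Displacement in mm.
#' @export
invert_force_law <- function(force, stiffness, toe_displacement) {
  if (force <= 0) return(0)
  if (toe_displacement <= 0) return(force / stiffness)
  upper <- force / stiffness + toe_displacement + 1
  stats::uniroot(function(x) force_law(x, stiffness, toe_displacement) - force,
                 c(0, upper), tol = 1e-12)$root
}

# Closed-form work integral of the law from 0 to X (N*mm = mJ).
work_under_law <- function(X, stiffness, toe_displacement) {
  xt <- toe_displacement
  if (xt <= 0) return(stiffness * X^2 / 2)
  stiffness * (X^2 / 2 - xt * X + xt^2 * (1 - exp(-X / xt)))
}
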