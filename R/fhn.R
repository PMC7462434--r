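#' FitzHugh-Nagumo parameters
#'
#' The two-variable excitable membrane model used for every cable: a fast
#' cubic voltage variable `v` and a slow linear recovery variable `w`.
#' Defaults (`a = 0.7`, `b = 0.5`, `eps = 0.1`) give a class-1 excitable
#' membrane with a single stable rest state and a refractory period.
#'
#' @param a recovery offset (dimensionless).
#' @param b recovery decay rate (dimensionless, > 0).
#' @param eps timescale separation between `v` and `w` (> 0).
#' @return classed list `ephapse_fhn`.
#' @export
fhn_params <- function(a = 0.7, b = 0.5, eps = 0.1) {
  if (!is.finite(a)) stop("`a` must be finite", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("`b` must be positive", call. = FALSE)
  if (!is.finite(eps) || eps <= 0) stop("`eps` must be positive", call. = FALSE)
  structure(list(a = a, b = b, eps = eps), class = "ephapse_fhn")
}

#' FitzHugh-Nagumo reaction terms
#'
#' Evaluates the membrane nonlinearity `f(v, w) = -(v - v^3/3 - w)` and the
#' recovery rate `dw/dt = eps (v + a - b w)` elementwise. The sign of `f` is
#' fixed so that the uncoupled nondimensional cable reads
#' `dv/dt = d2v/dz2 - f(v, w) + I`, i.e. the standard excitable
#' FitzHugh-Nagumo cable with cubic self-excitation `v - v^3/3`.
#'
#' @param v,w numeric arrays of identical shape.
#' @param params an [fhn_params()] object.
#' @return list with elements `f` and `w_rate`, the same shape as `v`.
#' @export
fhn_reaction <- function(v, w, params = fhn_params()) {
  if (!identical(dim(v), dim(w)) || length(v) != length(w))
    stop("`v` and `w` must have the same shape", call. = FALSE)
  list(f = -(v - v^3 / 3 - w),
       w_rate = params$eps * (v + params$a - params$b * w))
}

#' Resting state of the point FitzHugh-Nagumo model
#'
#' Solves the nullcline intersection `v - v^3/3 = (v + a)/b`,
#' `w = (v + a)/b` for the spatially uniform rest state shared by both
#' solvers as initial condition. For the default parameters the cubic
#' `v^3 + 3(1/b - 1) v + 3 a/b = 0` has a unique real root,
#' `v* = -1.0328...`, `w* = -0.6656...`. If a parameter choice yields three
#' real intersections, the most negative (the classical "down" state) is
#' returned with a warning.
#'
#' @param params an [fhn_params()] object.
#' @return list with `v_star`, `w_star`.
#' @export
resting_state <- function(params = fhn_params()) {
  a <- params$a; b <- params$b
  # v - v^3/3 - (v + a)/b = 0  <=>  v^3 + 3 (1 - b)/b * ... rearranged:
  # -v^3/3 + v (1 - 1/b) - a/b = 0  =>  v^3 + 3 (1/b - 1) v + 3 a / b = 0
  roots <- polyroot(c(3 * a / b, 3 * (1 / b - 1), 0, 1))
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(roots))])
  if (length(real) == 0L) stop("no real rest state found", call. = FALSE)
  if (length(real) > 1L)
    warning("multiple nullcline intersections; returning the most negative",
            call. = FALSE)
  v_star <- min(real)
  # polish with Newton steps on g(v) = v^3 + 3(1/b - 1) v + 3 a / b
  for (k in 1:6) {
    g  <- v_star^3 + 3 * (1 / b - 1) * v_star + 3 * a / b
    dg <- 3 * v_star^2 + 3 * (1 / b - 1)
    if (abs(dg) < .Machine$double.eps) break
    v_star <- v_star - g / dg
  }
  list(v_star = v_star, w_star = (v_star + a) / b)
}

#' Linear stability of the rest state
#'
#' Jacobian eigenvalues of the point (space-clamped) model at rest. Used as
#' a construction-time guard: simulations start from rest, so a rest state
#' that is a spiral source would invalidate the quiescent baseline.
#'
#' @param params an [fhn_params()] object.
#' @return complex eigenvalue pair of the 2x2 Jacobian.
#' @keywords internal
rest_state_eigenvalues <- function(params = fhn_params()) {
  rs <- resting_state(params)
  J <- matrix(c(1 - rs$v_star^2, -1,
                params$eps, -params$eps * params$b),
              2, 2, byrow = TRUE)
  eigen(J, only.values = TRUE)$values
}
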