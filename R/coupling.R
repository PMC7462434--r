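#' Build the ephaptic coupling matrix for a sheet of N axons
#'
#' Constructs the tridiagonal operator `A` that links the transmembrane
#' currents of `n_axons` parallel axons sharing a resistive extracellular
#' space, together with its dense inverse `alpha` (the pairwise ephaptic
#' coupling strengths) and the effective diffusion matrix
#' `B = 4 (R + 1) alpha` used by the discrete sheet solver.
#'
#' `A` has constant diagonal `D = 4 (R + 1/2)` and unit off-diagonals; the
#' first and last rows carry a single off-diagonal entry (the edge axons see
#' extracellular space on one side only). Its inverse couples every pair of
#' axons, with strength alternating in sign and decaying with lateral
#' separation, so the model is genuinely all-to-all rather than
#' nearest-neighbour. As the resistance ratio `R = r_a / r_e` grows, the
#' extracellular path becomes relatively conductive, `B` tends to the
#' identity, and the axons decouple into independent cables.
#'
#' @param n_axons number of axons (positive integer).
#' @param R resistance ratio `r_a / r_e`, strictly positive; smaller values
#'   mean stronger ephaptic coupling.
#' @return An object of class `ephapse_coupling`: a list with elements
#'   `n`, `R`, `D` (diagonal entry), `A`, `alpha` (= `solve(A)`), and
#'   `B` (= `4 (R + 1) alpha`).
#' @examples
#' cm <- build_coupling_matrix(5, R = 0.4)
#' cm$alpha[1, ]          # coupling of axon 1 to all axons
#' @export
build_coupling_matrix <- function(n_axons, R) {
  if (length(n_axons) != 1L || !is.finite(n_axons) || n_axons < 1 ||
      n_axons != round(n_axons))
    stop("`n_axons` must be a positive integer", call. = FALSE)
  if (length(R) != 1L || !is.finite(R) || R <= 0)
    stop("`R` must be a strictly positive number", call. = FALSE)
  n <- as.integer(n_axons)
  D <- 4 * (R + 0.5)
  A <- diag(D, n)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    A[cbind(idx, idx + 1L)] <- 1
    A[cbind(idx + 1L, idx)] <- 1
  }
  alpha <- solve(A)
  alpha <- (alpha + t(alpha)) / 2  # enforce exact symmetry
  structure(
    list(n = n, R = R, D = D, A = A, alpha = alpha,
         B = 4 * (R + 1) * alpha),
    class = "ephapse_coupling")
}

#' @export
print.ephapse_coupling <- function(x, ...) {
  cat(sprintf("Ephaptic coupling operator: %d axons, R = %g (D = %g)\n",
              x$n, x$R, x$D))
  cat(sprintf("  nearest-neighbour coupling alpha[1,2] = %.5g\n",
              if (x$n > 1) x$alpha[1, 2] else NA_real_))
  invisible(x)
}

#' Closed-form entry of the inverse coupling matrix
#'
#' Evaluates entry `(p, s)` of the inverse of the symmetric tridiagonal
#' matrix with constant diagonal `D` and unit off-diagonals, via the
#' continuant (three-term) recurrence `theta_i = D theta_{i-1} - theta_{i-2}`:
#' `alpha_ps = (-1)^(p+s) theta_{p-1} theta_{n-s} / theta_n` for `p <= s`.
#' This is the classical explicit tridiagonal-inverse formula; it serves as
#' an independent oracle for [build_coupling_matrix()], which inverts `A`
#' numerically.
#'
#' @param n matrix order (positive integer).
#' @param D diagonal entry; must exceed 2 so that the matrix is strictly
#'   diagonally dominant and the continuants are positive.
#' @param p,s 1-based row and column indices.
#' @return the scalar `alpha[p, s]`.
#' @export
closed_form_inverse_entry <- function(n, D, p, s) {
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  if (D <= 2) stop("`D` must exceed 2", call. = FALSE)
  if (p < 1 || p > n || s < 1 || s > n || p != round(p) || s != round(s))
    stop("indices out of range", call. = FALSE)
  if (p > s) { tmp <- p; p <- s; s <- tmp }
  # theta[k+1] = continuant of the leading k x k block; theta_0 = 1
  theta <- numeric(n + 1L)
  theta[1L] <- 1
  theta[2L] <- D
  if (n > 1L) for (k in 2L:n) theta[k + 1L] <- D * theta[k] - theta[k - 1L]
  (-1)^(p + s) * theta[p] * theta[n - s + 1L] / theta[n + 1L]
}

#' Map physical cable parameters to the nondimensional model parameters
#'
#' Converts measured per-unit-length cable constants into the two
#' dimensionless parameters the models take: the resistance ratio
#' `R = r_a / r_e = (1 / rho) (A_e / A_a)` of the discrete sheet model and
#' the lateral coupling constant `K = (delta^2 / lambda^2) / (R + 1)` of the
#' continuum field model. Also returns the scale factors of the
#' nondimensionalization, `z_scale = sqrt(g (r_a + r_e))` (axial length) and
#' `t_scale = g / c` (time), so physical axial positions and times map to
#' model units as `z_model = z_scale * z` and `t_model = t_scale * t`.
#'
#' @param phys a list (see [physical_parameters()]) with fields `r_a`, `r_e`,
#'   `c`, `g`, `delta`, `lam`, `rho`, `A_e`, `A_a`, all strictly positive.
#' @return list with `R`, `K`, `delta2_over_lam2`, `z_scale`, `t_scale`.
#' @export
physical_to_nondimensional <- function(phys) {
  phys <- physical_parameters(phys)
  R <- (1 / phys$rho) * (phys$A_e / phys$A_a)
  d2l2 <- (phys$delta / phys$lam)^2
  list(R = R,
       K = d2l2 / (R + 1),
       delta2_over_lam2 = d2l2,
       z_scale = sqrt(phys$g * (phys$r_a + phys$r_e)),
       t_scale = phys$g / phys$c)
}

#' Validate a set of physical cable parameters
#'
#' Checks positivity of all fields and warns when the extracellular-to-
#' intracellular resistivity ratio `rho` lies outside the physiologically
#' plausible band of 1 to 4.
#'
#' @param phys named list with fields `r_a`, `r_e`, `c`, `g`, `delta`,
#'   `lam`, `rho`, `A_e`, `A_a`.
#' @return the validated list, classed `ephapse_physical`.
#' @export
physical_parameters <- function(phys) {
  need <- c("r_a", "r_e", "c", "g", "delta", "lam", "rho", "A_e", "A_a")
  missing <- setdiff(need, names(phys))
  if (length(missing))
    stop("missing physical parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (f in need) {
    val <- phys[[f]]
    if (length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("physical parameter `%s` must be a positive number", f),
           call. = FALSE)
  }
  if (phys$rho < 1 || phys$rho > 4)
    warning(sprintf(
      "rho = %g lies outside the plausible resistivity-ratio band [1, 4]",
      phys$rho), call. = FALSE)
  structure(phys[need], class = "ephapse_physical")
}

#' Nondimensional model parameters
#'
#' Lightweight validated container for the discrete-model resistance ratio
#' `R` and the continuum lateral coupling constant
#' `K = delta2_over_lam2 / (R + 1)`.
#'
#' @param R resistance ratio, strictly positive.
#' @param delta2_over_lam2 squared ratio of interaxonal spacing to the
#'   lateral characteristic length; default 0.01 (spacing much smaller than
#'   an axon diameter).
#' @return list with `R`, `K`, `delta2_over_lam2`.
#' @export
nondimensional_params <- function(R, delta2_over_lam2 = 0.01) {
  if (!is.finite(R) || R <= 0) stop("`R` must be positive", call. = FALSE)
  if (!is.finite(delta2_over_lam2) || delta2_over_lam2 < 0)
    stop("`delta2_over_lam2` must be nonnegative", call. = FALSE)
  list(R = R, K = delta2_over_lam2 / (R + 1),
       delta2_over_lam2 = delta2_over_lam2)
}
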