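#' Simulate the discrete sheet of N ephaptically coupled cables
#'
#' Integrates the nondimensional sheet model
#' \deqn{\partial v_p/\partial t = 4(R+1)\sum_s \alpha_{ps}\,
#'       \partial^2 v_s/\partial z^2 + v_p - v_p^3/3 - w_p + I_p,}
#' \deqn{\partial w_p/\partial t = \epsilon (v_p + a - b w_p),}
#' from uniform rest, with the all-to-all coupling matrix `alpha` from
#' [build_coupling_matrix()]. Time stepping is Crank-Nicolson on the linear
#' coupled-diffusion operator (solved exactly in the lateral eigenbasis of
#' `B = 4(R+1) alpha`, one tridiagonal solve along `z` per mode) with
#' explicit treatment of the cubic reaction, the recovery equation, and the
#' stimulus. Zero-flux boundaries in `z` use second-order mirrored ghost
#' nodes; the lateral edges are encoded in the first/last rows of `A`.
#'
#' @param grid a [grid_spec()]; if `z_extent` is `NULL` it is auto-sized
#'   from the measured pulse speed so impulses cannot reach the far
#'   boundary before `t_end`.
#' @param R resistance ratio (strictly positive); smaller = stronger
#'   ephaptic coupling.
#' @param fhn an [fhn_params()].
#' @param protocol an `ephapse_protocol` (see [impulse_protocol()]).
#' @param record_z `NULL` to record the full axial grid at each snapshot,
#'   or a numeric vector of axial positions (snapped to grid nodes) to
#'   record only those columns (memory-light, for long spike-train runs).
#' @param record_w also store the recovery field at snapshots.
#' @param reaction_on test hook; `FALSE` integrates the pure linear
#'   diffusion operator (used by conservation checks).
#' @return an `ephapse_result` with snapshot array `v` of dimension
#'   `(n_lateral, n_recorded_z, n_snapshots)`, snapshot `times`, the
#'   recorded axial coordinates `z`, and full provenance (grid, parameters,
#'   protocol echo, model tag).
#' @export
simulate_discrete <- function(grid, R, fhn = fhn_params(), protocol,
                              record_z = NULL, record_w = FALSE,
                              reaction_on = TRUE) {
  lat <- lateral_eigen_discrete(grid$n_lateral, R)
  cp <- list(R = R, D = 4 * (R + 0.5))
  if (!is.null(lat$alpha)) cp$alpha <- lat$alpha
  run_sheet(grid, lat, fhn, protocol, record_z, record_w, reaction_on,
            model = "discrete", coupling = cp)
}

#' Simulate the continuum field model of the axon sheet
#'
#' Integrates the continuous-limit field equations
#' \deqn{\partial^2 v/\partial z^2 = i + K\, \partial^2 i/\partial x^2,
#'       \qquad i = \partial v/\partial t - (v - v^3/3 - w) - I,}
#' \deqn{\partial w/\partial t = \epsilon (v + a - b w),}
#' in which the membrane-current field `i` is obtained each step by solving
#' the lateral Helmholtz-type relation `(1 + K d2/dx2) i = d2v/dz2`
#' implicitly (zero flux in `x`), after which `v` advances by
#' Crank-Nicolson on the composite linear operator and explicit reaction.
#' `K = 0` decouples the columns into independent cables.
#'
#' @param K lateral coupling constant (nonnegative).
#' @inheritParams simulate_discrete
#' @inherit simulate_discrete return
#' @export
simulate_continuum <- function(grid, K, fhn = fhn_params(), protocol,
                               record_z = NULL, record_w = FALSE,
                               reaction_on = TRUE) {
  lat <- lateral_eigen_continuum(grid$n_lateral, grid$dx, K)
  run_sheet(grid, lat, fhn, protocol, record_z, record_w, reaction_on,
            model = "continuum", coupling = list(K = K))
}

# lateral operator eigen-factorizations ------------------------------------

# discrete sheet: B = 4(R+1) A^{-1}, symmetric positive definite
lateral_eigen_discrete <- function(n, R) {
  if (n == 1L)
    return(list(Q = matrix(1), Qinv = matrix(1),
                d = 4 * (R + 1) / (4 * R + 2)))
  cm <- build_coupling_matrix(n, R)
  e <- eigen(cm$B, symmetric = TRUE)
  list(Q = e$vectors, Qinv = t(e$vectors), d = e$values, alpha = cm$alpha)
}

# continuum: effective axial diffusivity per lateral mode is
# 1 / (1 + K mu), mu an eigenvalue of the zero-flux lateral Laplacian.
# The mirrored-ghost Neumann matrix is non-symmetric in its edge rows but
# similar to a symmetric one via diag(1/sqrt(2), 1, ..., 1, 1/sqrt(2)).
lateral_eigen_continuum <- function(n, dx, K) {
  if (!is.finite(K) || K < 0) stop("`K` must be nonnegative", call. = FALSE)
  if (n == 1L || K == 0)
    return(list(Q = diag(n), Qinv = diag(n), d = rep(1, n)))
  s <- rep(1, n); s[c(1, n)] <- 1 / sqrt(2)
  Ls <- neumann_laplacian(n, dx)
  Ls <- diag(s) %*% Ls %*% diag(1 / s)
  Ls <- (Ls + t(Ls)) / 2
  e <- eigen(Ls, symmetric = TRUE)
  denomK <- 1 + K * e$values
  if (any(abs(denomK) < 1e-8))
    stop(paste("lateral operator is resonant: an eigenvalue of",
               "(1 + K d2/dx2) vanishes; change K or dx"), call. = FALSE)
  Q <- diag(1 / s) %*% e$vectors
  Qinv <- t(e$vectors) %*% diag(s)
  list(Q = Q, Qinv = Qinv, d = 1 / denomK, mu = e$values)
}

# 1D second-difference matrix with mirrored-ghost zero-flux rows
neumann_laplacian <- function(n, h) {
  L <- diag(-2, n)
  if (n > 1L) {
    idx <- seq_len(n - 1L)
    L[cbind(idx, idx + 1L)] <- 1
    L[cbind(idx + 1L, idx)] <- 1
    L[1, 2] <- 2
    L[n, n - 1L] <- 2
  }
  L / h^2
}

# shared driver -------------------------------------------------------------

run_sheet <- function(grid, lat, fhn, protocol, record_z, record_w,
                      reaction_on, model, coupling) {
  if (is.null(grid$z_extent)) {
    sp <- estimate_pulse_speed(grid = grid, fhn = fhn)
    # lead impulses in coupled regimes run up to ~25% faster than a single
    # cable (lateral feed-forward); 1.3x the single-cable speed bounds them
    bound <- sp$speed * 1.3
    z_ext <- ceiling((bound * grid$t_end + 10) / grid$dz) * grid$dz
    grid$z_extent <- z_ext
  }
  nz <- n_z_nodes(grid)
  z <- z_coords(grid)
  validate_protocol(protocol, grid)
  rs <- resting_state(fhn)
  ev <- protocol$events
  emat <- if (nrow(ev)) {
    j0 <- vapply(ev$z_min, function(zm) min(which(z >= zm - 1e-12)), 1L)
    j1 <- vapply(ev$z_max, function(zm) max(which(z <= zm + 1e-12)), 1L)
    cbind(ev$lateral_index - 1L, ev$onset, ev$duration, ev$amplitude,
          j0 - 1L, j1 - 1L)
  } else matrix(0, 0, 6)

  rec_idx <- if (is.null(record_z)) seq_len(nz) - 1L else {
    ri <- vapply(record_z, function(zz) which.min(abs(z - zz)), 1L)
    sort(unique(ri)) - 1L
  }
  n_steps <- as.integer(round(grid$t_end / grid$dt))
  stride <- as.integer(round(grid$snapshot_every / grid$dt))

  v0 <- matrix(rs$v_star, grid$n_lateral, nz)
  w0 <- matrix(rs$w_star, grid$n_lateral, nz)
  t_wall <- proc.time()[["elapsed"]]
  out <- cn_imex_core(v0, w0, lat$Q, lat$Qinv, lat$d,
                      grid$dz, grid$dt, n_steps,
                      fhn$a, fhn$b, fhn$eps, emat, stride, rec_idx,
                      record_w, reaction_on, 0)
  t_wall <- proc.time()[["elapsed"]] - t_wall
  coupling$condition_number <- max(abs(lat$d)) / min(abs(lat$d))
  timing <- list(elapsed_s = t_wall,
                 s_per_1000_steps = 1000 * t_wall / n_steps)
  structure(list(
    model = model, coupling = coupling,
    times = as.numeric(out$times),
    v = out$v,
    w = if (record_w) out$w else NULL,
    v_final = out$v_final, w_final = out$w_final,
    z = z[rec_idx + 1L], grid = grid, fhn = fhn,
    protocol = protocol, protocol_json = as.character(protocol_to_json(protocol)),
    resting = rs, timing = timing,
    package_version = as.character(utils::packageVersion("ephapse"))),
    class = "ephapse_result")
}

validate_protocol <- function(protocol, grid) {
  ev <- protocol$events
  if (!nrow(ev)) return(invisible(TRUE))
  if (any(ev$lateral_index > grid$n_lateral))
    stop("protocol error: lateral index outside the grid", call. = FALSE)
  if (any(ev$onset >= grid$t_end))
    stop("protocol error: event onset at or beyond t_end", call. = FALSE)
  if (any(ev$z_min < 0) || any(ev$z_max > grid$z_extent))
    stop("protocol error: stimulus z-window outside the domain", call. = FALSE)
  if (any(ev$z_max < ev$z_min))
    stop("protocol error: empty stimulus z-window", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ephapse_result <- function(x, ...) {
  cat(sprintf(
    "ephapse %s-model run: %d lateral x %d z-nodes recorded, %d snapshots to t = %g\n",
    x$model, dim(x$v)[1], dim(x$v)[2], length(x$times), max(x$times)))
  cp <- if (x$model == "discrete") sprintf("R = %g", x$coupling$R)
        else sprintf("K = %g", x$coupling$K)
  cat(sprintf("  coupling %s; %d stimulus event(s)\n", cp,
              nrow(x$protocol$events)))
  invisible(x)
}

# dense reference stepping ---------------------------------------------------

#' Assemble the full linear operator as one dense matrix
#'
#' Builds the (lateral x axial) coupled-diffusion operator as a single
#' dense matrix over the flattened state `vec(v)` (column-major,
#' lateral-fastest). Discrete model: `kron(Lz, B)`; continuum:
#' `kron(Lz, (I + K Lxx)^{-1})`. Intended only for the brute-force
#' reference stepper on small grids.
#'
#' @param model `"discrete"` or `"continuum"`.
#' @param grid a [grid_spec()] with `z_extent` set.
#' @param R,K the coupling parameter for the chosen model.
#' @return dense matrix of order `n_lateral * n_z`.
#' @export
dense_operator <- function(model = c("discrete", "continuum"), grid,
                           R = NULL, K = NULL) {
  model <- match.arg(model)
  nz <- n_z_nodes(grid)
  if (grid$n_lateral > 20 || nz > 100)
    stop("dense reference operator restricted to grids <= 20 x 100 nodes",
         call. = FALSE)
  Lz <- neumann_laplacian(nz, grid$dz)
  P <- if (model == "discrete") {
    build_coupling_matrix(grid$n_lateral, R)$B
  } else {
    if (K == 0) diag(grid$n_lateral)
    else solve(diag(grid$n_lateral) +
                 K * neumann_laplacian(grid$n_lateral, grid$dx))
  }
  kronecker(Lz, P)
}

#' One brute-force IMEX Crank-Nicolson step
#'
#' Advances a field state by a single step using the full dense linear
#' system, mirroring the production scheme exactly: explicit reaction and
#' stimulus, Crank-Nicolson on the dense operator, forward-Euler recovery
#' from the pre-step voltage. Bit-for-bit deterministic; the independent
#' oracle for the production eigenbasis fast path.
#'
#' @param state list with matrices `v`, `w` (`n_lateral x n_z`) and time `t`.
#' @param M dense operator from [dense_operator()].
#' @param dt time step (`0` returns the state unchanged).
#' @param fhn an [fhn_params()].
#' @param protocol an `ephapse_protocol` (evaluated at the pre-step time).
#' @param grid the matching [grid_spec()].
#' @param reaction_on test hook, as in [simulate_discrete()].
#' @return updated state list.
#' @export
dense_reference_step <- function(state, M, dt, fhn = fhn_params(),
                                 protocol, grid, reaction_on = TRUE) {
  if (dt == 0) return(state)
  v <- state$v; w <- state$w
  nl <- nrow(v); nz <- ncol(v)
  vv <- as.numeric(v)
  rhs <- vv + (dt / 2) * (M %*% vv)
  if (reaction_on) rhs <- rhs + dt * as.numeric(v - v^3 / 3 - w)
  I <- evaluate_stimulus(protocol, state$t, grid)
  rhs <- rhs + dt * as.numeric(I)
  v_new <- solve(diag(nl * nz) - (dt / 2) * M, rhs)
  w_new <- w + dt * fhn$eps * (v + fhn$a - fhn$b * w)
  list(v = matrix(v_new, nl, nz), w = w_new, t = state$t + dt)
}

# pulse speed ----------------------------------------------------------------

#' Measure the traveling-pulse speed of a single cable
#'
#' Launches one default impulse on an isolated (uncoupled) cable and
#' regresses the front position -- the largest axial coordinate where `v`
#' exceeds `threshold` -- against time over the latter half of the run.
#' Used to auto-size `z_extent` so impulses never reach the far boundary;
#' for coupled sheets the bound is scaled by the square root of the largest
#' lateral-mode diffusivity.
#'
#' @param grid a [grid_spec()]; only `dz` and `dt` are used (the probe run
#'   has its own horizon).
#' @param fhn an [fhn_params()].
#' @param threshold front-detection level (default 0).
#' @param t_probe probe-run duration.
#' @return list with `speed` (model units), the per-snapshot front
#'   `positions` and `times` used for the fit, and the regression residual
#'   standard deviation.
#' @export
estimate_pulse_speed <- function(grid = grid_spec(), fhn = fhn_params(),
                                 threshold = 0, t_probe = 120) {
  g <- grid_spec(n_lateral = 1, z_extent = ceiling(3 * t_probe / grid$dz) *
                   grid$dz, dz = grid$dz, dx = grid$dx, dt = grid$dt,
                 t_end = t_probe, snapshot_every = 1)
  prot <- impulse_protocol(list(c(1, 0)))
  res <- run_sheet(g, list(Q = matrix(1), Qinv = matrix(1), d = 1),
                   fhn, prot, record_z = NULL, record_w = FALSE,
                   reaction_on = TRUE, model = "discrete",
                   coupling = list(R = Inf))
  pos <- apply(res$v[1, , , drop = TRUE], 2, function(col) {
    above <- which(col > threshold)
    if (length(above)) max(res$z[above]) else NA_real_
  })
  keep <- which(!is.na(pos) & res$times > t_probe / 2)
  if (length(keep) < 5)
    stop("propagation failure: no traveling impulse detected", call. = FALSE)
  fit <- stats::lm(pos[keep] ~ res$times[keep])
  speed <- unname(stats::coef(fit)[2])
  if (!is.finite(speed) || speed <= 0)
    stop("propagation failure: nonpositive front speed", call. = FALSE)
  list(speed = speed, positions = pos[keep], times = res$times[keep],
       residual_sd = stats::sd(stats::residuals(fit)))
}
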