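#' Space-time discretization for a sheet simulation
#'
#' Describes the lateral x axial x time grid shared by both models. The
#' lateral dimension indexes axons (discrete model) or field columns
#' (continuum model); the axial coordinate `z` runs along the fibers.
#' Defaults follow the reference discretization: `dt = 0.05`, `dz = 0.5`,
#' `dx = 1`, 50 lateral nodes.
#'
#' @param n_lateral number of axons / lateral columns (>= 2 for coupling to
#'   be meaningful; 1 is allowed for single-cable runs).
#' @param z_extent axial domain length (model units). `NULL` requests
#'   auto-sizing from the measured pulse speed at simulation time.
#' @param dz axial step.
#' @param dx lateral step (continuum model only).
#' @param dt time step.
#' @param t_end final time.
#' @param snapshot_every output cadence in time units; must be a multiple
#'   of `dt` (within rounding).
#' @return classed list `ephapse_grid`.
#' @export
grid_spec <- function(n_lateral = 50, z_extent = NULL, dz = 0.5, dx = 1,
                      dt = 0.05, t_end = 100, snapshot_every = 1.0) {
  stopifnot(n_lateral >= 1, n_lateral == round(n_lateral))
  for (nm in c("dz", "dx", "dt", "t_end", "snapshot_every")) {
    val <- get(nm)
    if (length(val) != 1L || !is.finite(val) || val <= 0)
      stop(sprintf("`%s` must be a positive number", nm), call. = FALSE)
  }
  if (!is.null(z_extent)) {
    if (!is.finite(z_extent) || z_extent <= 0)
      stop("`z_extent` must be positive (or NULL for auto-sizing)",
           call. = FALSE)
    if (abs(z_extent / dz - round(z_extent / dz)) > 1e-8)
      stop("`z_extent` must be an integer multiple of `dz`", call. = FALSE)
  }
  if (abs(t_end / dt - round(t_end / dt)) > 1e-8)
    stop("`t_end` must be an integer multiple of `dt`", call. = FALSE)
  stride <- snapshot_every / dt
  if (abs(stride - round(stride)) > 1e-6)
    stop("`snapshot_every` must be an integer multiple of `dt`", call. = FALSE)
  structure(list(n_lateral = as.integer(n_lateral), z_extent = z_extent,
                 dz = dz, dx = dx, dt = dt, t_end = t_end,
                 snapshot_every = snapshot_every),
            class = "ephapse_grid")
}

# number of axial nodes (z = 0, dz, ..., z_extent)
n_z_nodes <- function(grid) as.integer(round(grid$z_extent / grid$dz)) + 1L

# axial coordinates of the grid nodes
z_coords <- function(grid) seq(0, by = grid$dz, length.out = n_z_nodes(grid))
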