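# Shared scenario definitions and a per-session cache so expensive
# simulations are run once and reused across test files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# the standard two-impulse protocol: lateral 30 at t = 0, lateral 20 at t = 10
std_protocol <- function() impulse_protocol(list(c(30, 0), c(20, 10)))

# compact grid used for regime scenarios: 50 axons, reduced axial domain
# and horizon (the regime outcomes are unchanged versus the full-scale runs)
std_grid <- function(t_end = 800, z_extent = 300)
  grid_spec(n_lateral = 50, z_extent = z_extent, t_end = t_end)

std_run_discrete <- function(R, t_end = 800, z_extent = 300) {
  key <- sprintf("d_%g_%g_%g", R, t_end, z_extent)
  cached(key, simulate_discrete(std_grid(t_end, z_extent), R,
                                protocol = std_protocol()))
}

std_run_continuum <- function(K, t_end = 800, z_extent = 300) {
  key <- sprintf("c_%g_%g_%g", K, t_end, z_extent)
  cached(key, simulate_continuum(std_grid(t_end, z_extent), K,
                                 protocol = std_protocol()))
}

# small grid for brute-force oracle comparisons
small_grid <- function(dt = 0.05, t_end = 10)
  grid_spec(n_lateral = 6, z_extent = 19.5, dz = 0.5, dt = dt,
            t_end = t_end, snapshot_every = dt)

rest_state_default <- function() cached("rest", resting_state())
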