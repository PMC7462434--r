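#' Deterministic synthetic fixtures with embedded ground truth
#'
#' Generates small synthetic objects for exercising the analysis toolkit
#' without running full simulations; each carries the ground truth it was
#' built from.
#'
#' Kinds:
#' \describe{
#'   \item{`trace_with_spikes`}{a resting-level voltage trace with
#'     template action-potential pulses inserted at known times
#'     (`params$spike_times`, default `c(50, 120)`; `params$t_end`,
#'     `params$dt` control sampling). Ground truth: the inserted times and
#'     the exact threshold-crossing times.}
#'   \item{`raster_uniform`}{an `ephapse_raster` whose every node fires at
#'     a fixed interval (`params$interval`, default 10;
#'     `params$n_lateral`, `params$n_stations`, `params$n_spikes`).
#'     Ground truth: the interval.}
#'   \item{`snapshot_sinusoid`}{a minimal `ephapse_result`-shaped object
#'     whose single snapshot is a pure lateral sinusoid
#'     (`params$mode`, default 3, over `params$n_lateral` x
#'     `params$n_z`). Ground truth: the injected mode index.}
#' }
#'
#' @param kind one of `"trace_with_spikes"`, `"raster_uniform"`,
#'   `"snapshot_sinusoid"`.
#' @param params named list of kind-specific parameters (see above).
#' @param seed integer; fixes the small jitter used by
#'   `trace_with_spikes`.
#' @return a list with `data` (the synthetic object) and `ground_truth`.
#' @export
make_fixture <- function(kind, params = list(), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  rs <- resting_state()
  switch(kind,
    trace_with_spikes = {
      dt <- params$dt %||% 1
      t_end <- params$t_end %||% 200
      spike_times <- params$spike_times %||% c(50, 120)
      times <- seq(0, t_end, by = dt)
      v <- rep(rs$v_star, length(times))
      # template pulse: fast triangular upstroke to +1.9 over ~3 time
      # units, decay back over ~8 (an FHN-like action-potential envelope)
      shape_t <- c(0, 1.5, 3, 6, 11)
      shape_v <- c(rs$v_star, 0.5, 1.9, 0.3, rs$v_star)
      crossings <- numeric(length(spike_times))
      for (i in seq_along(spike_times)) {
        s0 <- spike_times[i]
        seg <- times >= s0 & times <= s0 + max(shape_t)
        v[seg] <- pmax(v[seg],
                       stats::approx(shape_t + s0, shape_v, times[seg])$y)
        # exact upward 0-crossing of the template
        crossings[i] <- s0 + stats::approx(shape_v[1:3], shape_t[1:3], 0)$y
      }
      list(data = list(trace = v, times = times),
           ground_truth = list(spike_times = spike_times,
                               crossing_times = crossings))
    },
    raster_uniform = {
      interval <- params$interval %||% 10
      nl <- params$n_lateral %||% 5
      ns <- params$n_stations %||% 4
      nspk <- params$n_spikes %||% 6
      spikes <- lapply(seq_len(nl), function(p)
        lapply(seq_len(ns), function(si)
          seq(0, by = interval, length.out = nspk)))
      raster <- structure(
        list(spikes = spikes, z_stations = seq(10, by = 20, length.out = ns),
             station_cols = seq_len(ns), n_lateral = nl,
             threshold = 0, refractory = 5,
             t_end = interval * nspk),
        class = "ephapse_raster")
      list(data = raster, ground_truth = list(interval = interval))
    },
    snapshot_sinusoid = {
      mode <- params$mode %||% 3
      nl <- params$n_lateral %||% 50
      nz <- params$n_z %||% 40
      x <- seq_len(nl) - 1
      snap <- matrix(sin(2 * pi * mode * x / nl), nl, nz)
      v <- array(snap, c(nl, nz, 1))
      result <- structure(
        list(model = "fixture", coupling = list(), times = 0, v = v,
             z = seq(0, by = 0.5, length.out = nz),
             grid = NULL, fhn = fhn_params(),
             protocol = impulse_protocol(list()), resting = rs),
        class = "ephapse_result")
      list(data = result, ground_truth = list(mode = mode))
    },
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
}
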