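#' Boxcar impulse protocol
#'
#' Builds a stimulation protocol from `(lateral_index, onset)` pairs, one
#' boxcar current-injection event per pair. The default event is the
#' reference inlet stimulus: amplitude `I = 2` applied for 2 time units over
#' the axial window `z` in `[0, 4]`, enough to launch exactly one action
#' potential on the targeted axon.
#'
#' @param pairs list of length-2 vectors `c(lateral_index, onset)`, or a
#'   2-column matrix (one row per event). May be empty.
#' @param duration,amplitude,z_window event shape shared by all events.
#' @param n_lateral if given, indices are validated against `[1, n_lateral]`.
#' @return an `ephapse_protocol` object (events data frame + generator tag).
#' @examples
#' impulse_protocol(list(c(30, 0), c(20, 10)))
#' @export
impulse_protocol <- function(pairs, duration = 2, amplitude = 2,
                             z_window = c(0, 4), n_lateral = NULL) {
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  events <- if (length(pairs) == 0L) {
    data.frame(lateral_index = integer(), onset = numeric(),
               duration = numeric(), amplitude = numeric(),
               z_min = numeric(), z_max = numeric())
  } else {
    idx <- vapply(pairs, function(p) as.numeric(p[[1]]), numeric(1))
    ons <- vapply(pairs, function(p) as.numeric(p[[2]]), numeric(1))
    if (any(idx < 1 | idx != round(idx)))
      stop("lateral indices must be positive integers", call. = FALSE)
    if (!is.null(n_lateral) && any(idx > n_lateral))
      stop("lateral index outside [1, n_lateral]", call. = FALSE)
    data.frame(lateral_index = as.integer(idx), onset = ons,
               duration = duration, amplitude = amplitude,
               z_min = z_window[1], z_max = z_window[2])
  }
  new_protocol(events, generator = "manual", seed = NULL)
}

#' Seeded Poisson spike-train protocol
#'
#' Gives every lateral index a finite train of impulses whose inter-onset
#' intervals follow a refractory-respecting Poisson process: each interval
#' is the minimum realizable gap (`duration + refractory_floor`, so no two
#' boxcar stimuli on one axon merge and the membrane can recover) plus an
#' exponential draw whose rate is set so that the intervals have exactly
#' the requested mean. The first onset of each train is uniform in
#' `[0, mean_interval]`. Fully reproducible from `seed`.
#'
#' @param n_lateral number of axons/columns to stimulate (all of them).
#' @param n_impulses impulses per axon (default 10).
#' @param mean_interval mean inter-impulse interval (default 10 time units).
#' @param seed integer seed.
#' @param duration,amplitude,z_window boxcar shape, as in
#'   [impulse_protocol()].
#' @param refractory_floor minimum quiet gap after an impulse before the
#'   next may start (default 5).
#' @param randomize_count if `TRUE`, the per-axon impulse count is drawn
#'   from a Poisson distribution with mean `n_impulses` (at least 1)
#'   instead of being fixed.
#' @return an `ephapse_protocol` object.
#' @export
poisson_train_protocol <- function(n_lateral, n_impulses = 10,
                                   mean_interval = 10, seed,
                                   duration = 2, amplitude = 2,
                                   z_window = c(0, 4),
                                   refractory_floor = 5,
                                   randomize_count = FALSE) {
  if (n_impulses < 1) stop("`n_impulses` must be >= 1", call. = FALSE)
  if (mean_interval <= 0) stop("`mean_interval` must be positive", call. = FALSE)
  min_gap <- duration + refractory_floor
  if (mean_interval <= min_gap)
    stop(sprintf(
      "mean_interval (%g) must exceed the minimum realizable gap (%g)",
      mean_interval, min_gap), call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ev <- vector("list", n_lateral)
  for (p in seq_len(n_lateral)) {
    k <- if (randomize_count) max(1L, stats::rpois(1, n_impulses)) else n_impulses
    onset <- stats::runif(1, 0, mean_interval)
    onsets <- numeric(k)
    onsets[1] <- onset
    if (k > 1L) for (j in 2:k) {
      gap <- min_gap + stats::rexp(1, rate = 1 / (mean_interval - min_gap))
      onsets[j] <- onsets[j - 1] + gap
    }
    ev[[p]] <- data.frame(lateral_index = p, onset = onsets,
                          duration = duration, amplitude = amplitude,
                          z_min = z_window[1], z_max = z_window[2])
  }
  events <- do.call(rbind, ev)
  new_protocol(events, generator = "poisson_train", seed = as.integer(seed))
}

new_protocol <- function(events, generator, seed) {
  events <- events[order(events$onset, events$lateral_index), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, generator = generator, seed = seed),
            class = "ephapse_protocol")
}

#' @export
print.ephapse_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol (%s): %d event(s)", x$generator,
              nrow(x$events)))
  if (!is.null(x$seed)) cat(sprintf(", seed %d", x$seed))
  cat("\n")
  if (nrow(x$events)) print(utils::head(x$events, 10))
  invisible(x)
}

#' Evaluate a protocol as a current field at one time
#'
#' Pure function returning the additive applied-current field `I(t)` on the
#' grid: each event contributes its amplitude on the nodes of its lateral
#' index whose axial coordinate lies in `[z_min, z_max]`, for
#' `t` in `[onset, onset + duration)`. Overlapping events sum.
#'
#' @param protocol an `ephapse_protocol`.
#' @param t time.
#' @param grid an [grid_spec()] with `z_extent` set.
#' @return matrix `n_lateral x n_z` of applied current.
#' @export
evaluate_stimulus <- function(protocol, t, grid) {
  z <- z_coords(grid)
  I <- matrix(0, grid$n_lateral, length(z))
  ev <- protocol$events
  if (!nrow(ev)) return(I)
  act <- which(ev$onset <= t & t < ev$onset + ev$duration)
  for (k in act) {
    cols <- which(z >= ev$z_min[k] - 1e-12 & z <= ev$z_max[k] + 1e-12)
    I[ev$lateral_index[k], cols] <- I[ev$lateral_index[k], cols] +
      ev$amplitude[k]
  }
  I
}

#' Serialize / restore a protocol as JSON
#'
#' Round-trips exactly: the JSON string embeds the event table, generator
#' tag and seed, and `protocol_from_json(protocol_to_json(p))` equals `p`.
#'
#' @param protocol an `ephapse_protocol`.
#' @return JSON string.
#' @export
protocol_to_json <- function(protocol) {
  jsonlite::toJSON(list(events = protocol$events,
                        generator = protocol$generator,
                        seed = protocol$seed),
                   digits = NA, auto_unbox = TRUE, null = "null")
}

#' @rdname protocol_to_json
#' @param json a string produced by [protocol_to_json()].
#' @export
protocol_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  ev <- as.data.frame(x$events)
  if (!nrow(ev))
    ev <- data.frame(lateral_index = integer(), onset = numeric(),
                     duration = numeric(), amplitude = numeric(),
                     z_min = numeric(), z_max = numeric())
  ev$lateral_index <- as.integer(ev$lateral_index)
  new_protocol(ev, generator = x$generator, seed = x$seed)
}

# save/restore .Random.seed so protocol generation does not perturb the
# caller's RNG stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
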