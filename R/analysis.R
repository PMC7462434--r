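#' Detect spikes in a single voltage trace
#'
#' Returns the times of upward threshold crossings, with linear
#' interpolation between samples, suppressing any crossing closer than
#' `refractory` to the previously accepted spike. The default threshold 0
#' sits midway between the rest potential (about -1.03) and the impulse
#' peak (about +1.9); the default refractory 5 is below the membrane's own
#' refractory period, so genuine consecutive impulses are never merged.
#'
#' @param trace numeric vector, the voltage sampled at `times`.
#' @param times numeric vector of uniform sample times.
#' @param threshold crossing level.
#' @param refractory minimum accepted inter-spike separation (time units).
#' @return sorted numeric vector of spike times (possibly empty).
#' @export
detect_spikes <- function(trace, times, threshold = 0, refractory = 5) {
  if (length(trace) != length(times))
    stop("`trace` and `times` must have equal length", call. = FALSE)
  n <- length(trace)
  if (n < 2L) return(numeric())
  up <- which(trace[-n] < threshold & trace[-1L] >= threshold)
  if (!length(up)) return(numeric())
  frac <- (threshold - trace[up]) / (trace[up + 1L] - trace[up])
  cand <- times[up] + frac * (times[up + 1L] - times[up])
  out <- cand[1L]
  for (tt in cand[-1L]) if (tt - out[length(out)] >= refractory) out <- c(out, tt)
  out
}

#' Build a spike raster from a simulation result
#'
#' Applies [detect_spikes()] at every (lateral index, axial station) node of
#' the snapshot array. Stations default to 10 equally spaced axial
#' positions that exclude the stimulus inlet region and the final 10% of
#' the domain (to avoid boundary effects); they are snapped to recorded
#' grid columns.
#'
#' @param result an `ephapse_result`.
#' @param z_stations axial positions to probe, or `NULL` for the default
#'   placement.
#' @param threshold,refractory passed to [detect_spikes()].
#' @return an `ephapse_raster`: spike-time lists indexed
#'   `spikes[[lateral]][[station]]`, plus `z_stations`, counts and
#'   detection settings.
#' @export
build_raster <- function(result, z_stations = NULL, threshold = 0,
                         refractory = 5) {
  cadence <- diff(result$times[1:2])
  if (cadence > refractory / 2)
    stop("sampling error: snapshot cadence exceeds refractory/2; spikes may be missed",
         call. = FALSE)
  Z <- max(result$z)
  if (is.null(z_stations)) {
    z_lo <- max(8, 0.05 * Z)
    z_stations <- seq(z_lo, 0.9 * Z, length.out = 10)
  }
  js <- vapply(z_stations, function(zz) which.min(abs(result$z - zz)), 1L)
  js <- unique(js)
  z_st <- result$z[js]
  nl <- dim(result$v)[1]
  spikes <- vector("list", nl)
  for (p in seq_len(nl)) {
    spikes[[p]] <- lapply(seq_along(js), function(si)
      detect_spikes(result$v[p, js[si], ], result$times, threshold, refractory))
  }
  structure(list(spikes = spikes, z_stations = z_st,
                 station_cols = js, n_lateral = nl,
                 threshold = threshold, refractory = refractory,
                 t_end = max(result$times)),
            class = "ephapse_raster")
}

#' @export
print.ephapse_raster <- function(x, ...) {
  n_sp <- sum(vapply(x$spikes, function(r) sum(lengths(r)), 1L))
  cat(sprintf("Spike raster: %d lateral x %d stations, %d spikes (threshold %g, refractory %g)\n",
              x$n_lateral, length(x$z_stations), n_sp, x$threshold,
              x$refractory))
  invisible(x)
}

# first spike time at (lateral p, station index si); NA if none
first_spike <- function(raster, p, si) {
  sp <- raster$spikes[[p]][[si]]
  if (length(sp)) sp[1L] else NA_real_
}

#' Impulse lag between two axons along the fiber
#'
#' For each axial station, the difference of first-spike times of the two
#' lateral indices (first minus second). A pair of non-interacting impulses
#' keeps a constant lag; ephaptic attraction/repulsion makes the lag drift
#' and then lock. The `locked_after` summary is the first station after
#' which the lag changes by less than 2% (with an absolute floor of 0.05
#' time units for near-zero lags) from station to station.
#'
#' @param raster an `ephapse_raster`.
#' @param pair two lateral indices.
#' @return list with `z` (stations kept), `lag` (time series over z),
#'   `locked_after` (station index or `NA`), `n_dropped` (stations missing
#'   a spike on either axon).
#' @export
measure_lag <- function(raster, pair) {
  stopifnot(length(pair) == 2)
  ns <- length(raster$z_stations)
  t1 <- vapply(seq_len(ns), function(si) first_spike(raster, pair[1], si), 1)
  t2 <- vapply(seq_len(ns), function(si) first_spike(raster, pair[2], si), 1)
  keep <- !is.na(t1) & !is.na(t2)
  n_dropped <- sum(!keep)
  if (n_dropped)
    warning(sprintf("%d station(s) dropped for missing spikes", n_dropped),
            call. = FALSE)
  lag <- (t1 - t2)[keep]
  z <- raster$z_stations[keep]
  locked_after <- NA_integer_
  if (length(lag) >= 2) {
    dl <- abs(diff(lag))
    tol <- pmax(0.02 * abs(lag[-length(lag)]), 0.05)
    flat <- dl < tol
    # first index from which all subsequent steps are flat
    run <- rev(cumprod(rev(flat)))
    idx <- which(run == 1)
    if (length(idx)) locked_after <- idx[1L]
  }
  list(z = z, lag = lag, locked_after = locked_after, n_dropped = n_dropped)
}

#' Width of co-traveling impulse fronts at a station
#'
#' Groups the lateral indices that spike at the given station into fronts:
#' laterally contiguous runs whose first-spike times lie within a locking
#' window of their neighbours. Returns one size per front, ordered by
#' lateral position. An isolated impulse gives a cluster of size 1; a
#' recruited front of three phase-locked impulses gives 3.
#'
#' @param raster an `ephapse_raster`.
#' @param z_station station position (snapped to the nearest raster
#'   station).
#' @param time_window maximum first-spike time difference between adjacent
#'   members of one front (default 5 time units).
#' @return integer vector of cluster sizes (empty if nothing spikes).
#' @export
front_width <- function(raster, z_station, time_window = 5) {
  si <- which.min(abs(raster$z_stations - z_station))
  tf <- vapply(seq_len(raster$n_lateral), function(p)
    first_spike(raster, p, si), 1)
  act <- which(!is.na(tf))
  if (!length(act)) return(integer())
  brk <- c(TRUE, diff(act) > 1 | abs(diff(tf[act])) > time_window)
  cl <- cumsum(brk)
  as.integer(table(cl))
}

#' Count retrograde (backward-traveling) spike chains
#'
#' Scans every lateral index for spike sequences whose arrival times
#' strictly decrease with increasing axial position across at least three
#' consecutive stations -- the signature of a wave traveling toward the
#' inlet. Simple forward-propagating regimes give 0; the complex
#' spatiotemporal regimes re-initiate impulses backward and give positive
#' counts.
#'
#' @param raster an `ephapse_raster` (needs >= 3 stations).
#' @param t_min only spikes at or after this time are considered (used to
#'   ignore a transient).
#' @param link_window maximum |time difference| for two spikes at adjacent
#'   stations to be considered the same wave (default 25 time units).
#' @return integer count of maximal backward chains.
#' @export
detect_backward_propagation <- function(raster, t_min = 0, link_window = 25) {
  ns <- length(raster$z_stations)
  if (ns < 3) stop("need at least 3 stations", call. = FALSE)
  total <- 0L
  for (p in seq_len(raster$n_lateral)) {
    rows <- lapply(raster$spikes[[p]], function(s) s[s >= t_min])
    # chain length ending at each spike, walking stations inlet -> outlet;
    # a backward link means the wave reached the previous (smaller-z)
    # station LATER than this one
    prev <- rows[[1L]]
    prev_len <- rep(1L, length(prev))
    for (j in 2:ns) {
      cur <- rows[[j]]
      cur_len <- rep(1L, length(cur))
      if (length(cur) && length(prev)) {
        for (m in seq_along(cur)) {
          dt <- prev - cur[m]           # > 0: arrived later at smaller z
          ok <- which(dt > 0 & dt <= link_window)
          if (length(ok))
            cur_len[m] <- max(prev_len[ok]) + 1L
        }
      }
      # each chain is counted exactly once, when it first spans 3 stations
      total <- total + sum(cur_len == 3L)
      prev <- cur
      prev_len <- cur_len
    }
  }
  total
}

#' Mean interspike interval table
#'
#' Per (lateral, station) node, the mean of consecutive spike-time
#' differences (the inverse of the mean firing rate); per station, the
#' average over lateral indices, ignoring nodes with fewer than two spikes
#' (their counts are reported). In the presence of significant ephaptic
#' coupling the station-averaged mISI of Poisson impulse trains decreases
#' with downstream distance, unlike the rate-conserving uncoupled cable.
#'
#' @param raster an `ephapse_raster`.
#' @return an `ephapse_misi`: `node` data frame (lateral, z, n_spikes,
#'   misi), `station` data frame (z, misi, n_nodes).
#' @export
compute_misi <- function(raster) {
  ns <- length(raster$z_stations)
  rows <- vector("list", raster$n_lateral * ns)
  k <- 0L
  for (p in seq_len(raster$n_lateral)) for (si in seq_len(ns)) {
    sp <- raster$spikes[[p]][[si]]
    k <- k + 1L
    rows[[k]] <- data.frame(
      lateral = p, z = raster$z_stations[si], n_spikes = length(sp),
      misi = if (length(sp) >= 2) mean(diff(sp)) else NA_real_)
  }
  node <- do.call(rbind, rows)
  station <- do.call(rbind, lapply(seq_len(ns), function(si) {
    sub <- node[node$z == raster$z_stations[si] & !is.na(node$misi), ]
    data.frame(z = raster$z_stations[si],
               misi = if (nrow(sub)) mean(sub$misi) else NA_real_,
               n_nodes = nrow(sub))
  }))
  structure(list(node = node, station = station), class = "ephapse_misi")
}

#' @export
print.ephapse_misi <- function(x, ...) {
  cat("Mean interspike intervals by axial station:\n")
  print(x$station, row.names = FALSE)
  invisible(x)
}

#' Spatial Fourier spectra of the snapshot sequence
#'
#' For every snapshot, the magnitude of the discrete Fourier transform of
#' the spatial pattern `v(lateral, axial)`, flattened in a fixed order.
#' The default is the full 2D DFT; `dims = "lateral"` transforms along the
#' lateral dimension only (a sensitivity variant).
#'
#' @param result an `ephapse_result` recorded on the full axial grid.
#' @param dims `"2d"` or `"lateral"`.
#' @return an `ephapse_spectrum`: `magnitude` matrix (modes x times),
#'   `times`, `shape` of the underlying grid, `dims`.
#' @export
spatial_spectrum <- function(result, dims = c("2d", "lateral")) {
  dims <- match.arg(dims)
  nt <- length(result$times)
  d <- dim(result$v)
  mag <- matrix(0, d[1] * d[2], nt)
  for (k in seq_len(nt)) {
    v <- result$v[, , k, drop = TRUE]
    if (is.null(dim(v))) v <- matrix(v, d[1], d[2])
    mag[, k] <- if (dims == "2d") as.numeric(Mod(stats::fft(v)))
                else as.numeric(Mod(stats::mvfft(v)))
  }
  structure(list(magnitude = mag, times = result$times,
                 shape = d[1:2], dims = dims),
            class = "ephapse_spectrum")
}

#' Cosine similarity between two spectrum series
#'
#' Per matched snapshot time, the cosine of the angle between the two
#' flattened magnitude spectra; plus its mean and standard deviation over
#' time. Snapshots where either spectrum has zero norm are dropped with a
#' warning.
#'
#' @param a,b `ephapse_spectrum` objects on matching grids and times.
#' @return list with `times`, `similarity`, `mean`, `sd`, `n_dropped`.
#' @export
spectrum_cosine_similarity <- function(a, b) {
  if (!identical(a$shape, b$shape))
    stop("spectra computed on different grid shapes", call. = FALSE)
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-8)
    stop("snapshot times do not match", call. = FALSE)
  na <- sqrt(colSums(a$magnitude^2))
  nb <- sqrt(colSums(b$magnitude^2))
  keep <- na > 0 & nb > 0
  n_dropped <- sum(!keep)
  if (n_dropped)
    warning(sprintf("%d snapshot(s) dropped for zero-norm spectrum", n_dropped),
            call. = FALSE)
  sim <- colSums(a$magnitude[, keep, drop = FALSE] *
                   b$magnitude[, keep, drop = FALSE]) / (na[keep] * nb[keep])
  sim <- pmin(pmax(sim, -1), 1)          # guard rounding past the bounds
  list(times = a$times[keep], similarity = sim,
       mean = mean(sim), sd = stats::sd(sim), n_dropped = n_dropped)
}

#' Classify the dynamical regime of a two-impulse scenario
#'
#' Operationalizes the qualitative regimes of the sheet models as a
#' decision tree over measured evidence from the spike raster:
#' \itemize{
#'   \item retrograde chains after the transient: `complex`;
#'   \item no recruitment beyond the stimulated axons: `independent`
#'     (constant lag) or `locked` (converged lag, adjacent stimulation);
#'   \item recruitment with a stable front size `k` and no retrograde
#'     chains: `front` (with `k >= 2`);
#'   \item growing lateral clusters without retrograde chains:
#'     `diffusive_front`.
#' }
#' Ambiguous evidence yields `complex` with `low_confidence = TRUE`,
#' never a silent answer.
#'
#' @param result an `ephapse_result` from a standard two-impulse run.
#' @param transient_frac fraction of the run treated as transient when
#'   counting retrograde chains (default 0.4).
#' @param time_window front-clustering window, as in [front_width()].
#' @return an `ephapse_regime`: `label`, front size `k` (when
#'   applicable), `low_confidence` flag, and the `evidence` list.
#' @export
classify_regime <- function(result, transient_frac = 0.4, time_window = 5) {
  raster <- build_raster(result)
  ns <- length(raster$z_stations)
  stim <- sort(unique(result$protocol$events$lateral_index))
  retro <- detect_backward_propagation(
    raster, t_min = transient_frac * raster$t_end)
  sizes_by_station <- lapply(seq_len(ns), function(si)
    front_width(raster, raster$z_stations[si], time_window))
  active_by_station <- vapply(seq_len(ns), function(si) {
    sum(vapply(seq_len(raster$n_lateral),
               function(p) length(raster$spikes[[p]][[si]]) > 0, TRUE))
  }, 1L)
  mid <- ceiling(ns / 2)
  evidence <- list(retro_chains = retro,
                   active_by_station = active_by_station,
                   cluster_sizes_mid = sizes_by_station[[mid]],
                   cluster_sizes_last = sizes_by_station[[ns]],
                   stimulated = stim)
  lab <- function(label, k = NA_integer_, low = FALSE)
    structure(list(label = label, k = k, low_confidence = low,
                   evidence = evidence), class = "ephapse_regime")

  if (retro > 0) return(lab("complex"))
  recruited <- any(active_by_station > length(stim))
  if (!recruited) {
    if (length(stim) == 2 && any(active_by_station == length(stim))) {
      lagres <- tryCatch(measure_lag(raster, stim),
                         warning = function(w) suppressWarnings(
                           measure_lag(raster, stim)))
      evidence$lag <- lagres$lag
      if (length(lagres$lag) >= 3) {
        rel_range <- diff(range(abs(lagres$lag))) /
          max(abs(lagres$lag), 0.05)
        evidence$lag_rel_range <- rel_range
        adjacent <- abs(diff(stim)) == 1
        la <- lagres$locked_after
        if (rel_range <= 0.05) return(lab("independent"))
        if (adjacent && !is.na(la) && la < length(lagres$lag))
          return(lab("locked"))
        return(lab("independent", low = rel_range > 0.10))
      }
    }
    return(lab(if (any(active_by_station > 0)) "independent" else "independent",
               low = all(active_by_station == 0)))
  }
  # recruitment: stable front vs laterally growing
  msize <- function(s) if (length(s)) max(s) else 0L
  m_mid <- msize(sizes_by_station[[mid]])
  m_last <- msize(sizes_by_station[[ns]])
  growth <- m_last - m_mid
  evidence$max_cluster_mid <- m_mid
  evidence$max_cluster_last <- m_last
  if (growth >= 2 || m_last >= 0.8 * raster$n_lateral)
    return(lab("diffusive_front", k = m_last))
  sizes <- sizes_by_station[[mid]]
  k_mode <- as.integer(names(sort(table(sizes), decreasing = TRUE))[1L])
  if (k_mode < 2) k_mode <- m_mid
  lab("front", k = k_mode)
}

#' @export
print.ephapse_regime <- function(x, ...) {
  cat(sprintf("Regime: %s%s%s\n", x$label,
              if (!is.na(x$k)) sprintf("(%d)", x$k) else "",
              if (x$low_confidence) " [low confidence]" else ""))
  cat(sprintf("  retrograde chains: %d; active per station: %s\n",
              x$evidence$retro_chains,
              paste(x$evidence$active_by_station, collapse = " ")))
  invisible(x)
}
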