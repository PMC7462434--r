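test_that("spike detection recovers inserted pulses and ignores rest", {
  rs <- rest_state_default()
  times <- seq(0, 200, by = 1)
  expect_identical(detect_spikes(rep(rs$v_star, 201), times), numeric())

  fx <- make_fixture("trace_with_spikes",
                     params = list(spike_times = c(50, 120)))
  sp <- detect_spikes(fx$data$trace, fx$data$times)
  expect_length(sp, 2)
  expect_lt(max(abs(sp - fx$ground_truth$crossing_times)), 1)

  # refractory suppression: two crossings closer than the dead time
  fx2 <- make_fixture("trace_with_spikes",
                      params = list(spike_times = c(50, 53)))
  expect_length(detect_spikes(fx2$data$trace, fx2$data$times,
                              refractory = 10), 1)

  # a single-impulse simulation yields exactly one spike mid-axon
  g <- grid_spec(n_lateral = 3, z_extent = 60, t_end = 50)
  res <- simulate_discrete(g, R = 0.8,
                           protocol = impulse_protocol(list(c(2, 0)),
                                                       n_lateral = 3))
  j <- which.min(abs(res$z - 30))
  expect_length(detect_spikes(res$v[2, j, ], res$times), 1)
  expect_length(detect_spikes(res$v[1, j, ], res$times), 0)
})

test_that("rasters mirror the scenario structure", {
  # rest run: empty raster
  g <- grid_spec(n_lateral = 4, z_extent = 60, t_end = 40)
  rest <- simulate_discrete(g, R = 0.8, protocol = impulse_protocol(list()))
  r0 <- build_raster(rest)
  expect_equal(sum(vapply(r0$spikes, function(x) sum(lengths(x)), 1L)), 0)

  # weak-coupling two-impulse run: exactly 2 nonempty rows everywhere
  res <- std_run_discrete(0.8)
  r <- build_raster(res)
  nonempty <- vapply(seq_len(r$n_lateral), function(p)
    all(lengths(r$spikes[[p]]) > 0), TRUE)
  expect_equal(which(nonempty), c(20L, 30L))

  # recruiting run: exactly 6 nonempty rows (two 3-wide fronts) downstream
  res4 <- std_run_discrete(0.4)
  r4 <- build_raster(res4)
  mid <- ceiling(length(r4$z_stations) / 2)
  active_mid <- which(vapply(seq_len(r4$n_lateral), function(p)
    length(r4$spikes[[p]][[mid]]) > 0, TRUE))
  expect_equal(active_mid, c(19L, 20L, 21L, 29L, 30L, 31L))

  # cadence guard
  g2 <- grid_spec(n_lateral = 2, z_extent = 20, t_end = 20,
                  snapshot_every = 4)
  res2 <- simulate_discrete(g2, R = 0.8, protocol = impulse_protocol(list()))
  expect_error(build_raster(res2), "sampling error")
})

test_that("lag measurement distinguishes symmetric, locked and independent pairs", {
  # mirror-symmetric simultaneous stimuli: zero lag at every station
  g <- grid_spec(n_lateral = 9, z_extent = 150, t_end = 120)
  prot <- impulse_protocol(list(c(4, 0), c(6, 0)), n_lateral = 9)
  res <- simulate_discrete(g, R = 0.8, protocol = prot)
  lg <- measure_lag(build_raster(res), c(4, 6))
  expect_true(all(abs(lg$lag) < 1e-9))

  # non-adjacent axons at weak coupling: constant lag (independence)
  lg2 <- measure_lag(build_raster(std_run_discrete(0.8)), c(30, 20))
  expect_lt(diff(range(lg2$lag)) / abs(mean(lg2$lag)), 0.05)
  expect_equal(lg2$locked_after, 1L)
})

test_that("front widths count co-traveling impulses", {
  # single impulse: cluster of size 1
  res1 <- std_run_discrete(0.8)
  r1 <- build_raster(res1)
  expect_equal(front_width(r1, 200), c(1L, 1L))

  # R = 0.4: both fronts have width 3
  expect_equal(front_width(build_raster(std_run_discrete(0.4)), 200),
               c(3L, 3L))
  # R = 0.33: both fronts have width 5
  expect_equal(front_width(build_raster(std_run_discrete(0.33)), 200),
               c(5L, 5L))
  # no spikes at the station: empty result
  g <- grid_spec(n_lateral = 4, z_extent = 60, t_end = 40)
  rest <- simulate_discrete(g, R = 0.8, protocol = impulse_protocol(list()))
  expect_length(front_width(build_raster(rest), 30), 0)
})

test_that("backward propagation is absent in simple regimes, present in complex", {
  expect_equal(detect_backward_propagation(build_raster(std_run_discrete(0.8))),
               0L)
  expect_equal(detect_backward_propagation(build_raster(std_run_discrete(0.4))),
               0L)
  expect_gt(detect_backward_propagation(build_raster(std_run_discrete(0.15))),
            0L)
})

test_that("mISI tables are exact on uniform rasters", {
  fx <- make_fixture("raster_uniform", params = list(interval = 10))
  m <- compute_misi(fx$data)
  expect_true(all(m$node$misi == 10))
  expect_true(all(m$station$misi == 10))
  expect_true(all(m$station$n_nodes == fx$data$n_lateral))

  # nodes with < 2 spikes are excluded but counted
  fx1 <- make_fixture("raster_uniform",
                      params = list(interval = 10, n_spikes = 1))
  m1 <- compute_misi(fx1$data)
  expect_true(all(is.na(m1$node$misi)))
  expect_true(all(m1$station$n_nodes == 0))
})

test_that("spatial spectra have the right support", {
  # uniform field: all energy in the zero mode
  rs <- rest_state_default()
  u <- make_fixture("snapshot_sinusoid", params = list(mode = 0))
  u$data$v[] <- rs$v_star
  su <- spatial_spectrum(u$data)
  expect_gt(su$magnitude[1, 1], 0)
  expect_lt(max(su$magnitude[-1, 1]), 1e-8 * su$magnitude[1, 1])

  # single lateral sinusoid: one symmetric mode pair
  fx <- make_fixture("snapshot_sinusoid", params = list(mode = 3))
  sx <- spatial_spectrum(fx$data, dims = "lateral")
  mag <- matrix(sx$magnitude[, 1], sx$shape[1], sx$shape[2])
  lat <- mag[, 1]
  nl <- sx$shape[1]
  peaks <- sort(order(lat, decreasing = TRUE)[1:2])
  expect_equal(peaks, c(3 + 1, nl - 3 + 1))   # modes +3 and -3 (1-based)
  expect_lt(max(lat[-peaks]), 1e-8 * max(lat))
})

test_that("spectrum cosine similarity satisfies its identities", {
  a <- std_run_discrete(0.4)
  sa <- spatial_spectrum(a)
  self <- spectrum_cosine_similarity(sa, sa)
  expect_true(all(abs(self$similarity - 1) < 1e-12))
  expect_true(all(self$similarity >= -1 & self$similarity <= 1))

  # disjoint spectral support: similarity 0
  f1 <- make_fixture("snapshot_sinusoid", params = list(mode = 3))
  f2 <- make_fixture("snapshot_sinusoid", params = list(mode = 7))
  s12 <- spectrum_cosine_similarity(spatial_spectrum(f1$data, "lateral"),
                                    spatial_spectrum(f2$data, "lateral"))
  expect_lt(abs(s12$mean), 1e-10)

  # shape mismatch is an error
  b <- make_fixture("snapshot_sinusoid", params = list(n_lateral = 10))
  expect_error(spectrum_cosine_similarity(sa, spatial_spectrum(b$data)),
               "shape")
})

test_that("the complex regime has broadband lateral content", {
  res <- std_run_discrete(0.19)
  sp <- spatial_spectrum(res, dims = "lateral")
  k <- length(res$times)
  mag <- matrix(sp$magnitude[, k], sp$shape[1], sp$shape[2])
  lat <- rowMeans(mag)
  expect_gt(sum(lat > 0.01 * max(lat)), 10)
})

test_that("the regime classifier reproduces the coupling progression", {
  expect_equal(classify_regime(std_run_discrete(0.8))$label, "independent")
  r4 <- classify_regime(std_run_discrete(0.4))
  expect_equal(r4$label, "front")
  expect_equal(r4$k, 3L)
  expect_equal(classify_regime(std_run_discrete(0.15))$label, "complex")
})

test_that("fixture generation is deterministic and validated", {
  f1 <- make_fixture("trace_with_spikes", seed = 5)
  f2 <- make_fixture("trace_with_spikes", seed = 5)
  expect_identical(f1, f2)
  expect_error(make_fixture("no_such_kind"), "unknown fixture kind")
})
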