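test_that("production fast path equals the dense brute-force stepper", {
  g <- small_grid()
  prot <- impulse_protocol(list(c(3, 0)), n_lateral = 6)
  rs <- rest_state_default()
  for (setup in list(list(model = "discrete", R = 0.5, K = NULL),
                     list(model = "continuum", R = NULL, K = 0.1))) {
    res <- if (setup$model == "discrete")
      simulate_discrete(g, R = setup$R, protocol = prot)
    else simulate_continuum(g, K = setup$K, protocol = prot)
    M <- dense_operator(setup$model, g, R = setup$R, K = setup$K)
    st <- list(v = matrix(rs$v_star, 6, 40),
               w = matrix(rs$w_star, 6, 40), t = 0)
    err <- 0
    for (n in 1:200) {
      st <- dense_reference_step(st, M, g$dt, protocol = prot, grid = g)
      err <- max(err, max(abs(st$v - res$v[, , n + 1])))
    }
    expect_lt(err, 1e-8)
  }
})

test_that("dense reference stepper fixed points: dt = 0 and rest", {
  g <- small_grid()
  prot <- impulse_protocol(list())
  rs <- rest_state_default()
  M <- dense_operator("discrete", g, R = 0.5)
  st <- list(v = matrix(rs$v_star, 6, 40), w = matrix(rs$w_star, 6, 40),
             t = 0)
  expect_identical(dense_reference_step(st, M, 0, protocol = prot, grid = g),
                   st)
  one <- dense_reference_step(st, M, g$dt, protocol = prot, grid = g)
  expect_lt(max(abs(one$v - rs$v_star)), 1e-12)
  expect_lt(max(abs(one$w - rs$w_star)), 1e-12)
  expect_error(dense_operator("discrete", grid_spec(n_lateral = 30,
                                                    z_extent = 100,
                                                    t_end = 10), R = 0.5),
               "restricted")
})

test_that("continuum at K = 0 decouples into independent cables", {
  g <- grid_spec(n_lateral = 5, z_extent = 60, t_end = 40)
  prot <- impulse_protocol(list(c(3, 0)), n_lateral = 5)
  res <- simulate_continuum(g, K = 0, protocol = prot)
  g1 <- grid_spec(n_lateral = 1, z_extent = 60, t_end = 40)
  single <- simulate_continuum(g1, K = 0,
                               protocol = impulse_protocol(list(c(1, 0)),
                                                           n_lateral = 1))
  # stimulated column equals the isolated cable exactly
  expect_lt(max(abs(res$v[3, , ] - single$v[1, , ])), 1e-10)
  # unstimulated columns never leave rest
  rs <- rest_state_default()
  expect_lt(max(abs(res$v[-3, , ] - rs$v_star)), 1e-10)
})

test_that("uniform-in-x stimulation evolves as a single cable", {
  # all columns stimulated identically: the lateral operator term vanishes
  g <- grid_spec(n_lateral = 6, z_extent = 60, t_end = 40)
  prot <- impulse_protocol(lapply(1:6, function(p) c(p, 0)), n_lateral = 6)
  res <- simulate_continuum(g, K = 0.1, protocol = prot)
  g1 <- grid_spec(n_lateral = 1, z_extent = 60, t_end = 40)
  single <- simulate_continuum(g1, K = 0,
                               protocol = impulse_protocol(list(c(1, 0)),
                                                           n_lateral = 1))
  for (p in 1:6)
    expect_lt(max(abs(res$v[p, , ] - single$v[1, , ])), 1e-10)
})

test_that("discrete model at very weak coupling matches independent cables", {
  g <- grid_spec(n_lateral = 8, z_extent = 80, t_end = 60)
  prot <- impulse_protocol(list(c(3, 0), c(6, 10)), n_lateral = 8)
  res <- simulate_discrete(g, R = 100, protocol = prot)
  g1 <- grid_spec(n_lateral = 1, z_extent = 80, t_end = 60)
  sing <- function(onset) {
    pr <- impulse_protocol(list(c(1, onset)), n_lateral = 1)
    simulate_discrete(g1, R = 100, protocol = pr)$v[1, , ]
  }
  expect_lt(max(abs(res$v[3, , ] - sing(0))), 1e-3)
  expect_lt(max(abs(res$v[6, , ] - sing(10))), 1e-3)
})

test_that("repeat runs are bit-identical", {
  g <- grid_spec(n_lateral = 10, z_extent = 50, t_end = 30)
  prot <- impulse_protocol(list(c(4, 0), c(7, 5)), n_lateral = 10)
  a <- simulate_discrete(g, R = 0.4, protocol = prot)
  b <- simulate_discrete(g, R = 0.4, protocol = prot)
  expect_identical(a$v, b$v)
  cc <- simulate_continuum(g, K = 0.15, protocol = prot)
  dd <- simulate_continuum(g, K = 0.15, protocol = prot)
  expect_identical(cc$v, dd$v)
})

test_that("pure coupled diffusion conserves the trapezoidal mass", {
  # reaction off: after the stimulus ends, the zero-flux diffusion
  # operator must conserve the z-trapezoid-weighted total of v for a
  # laterally centered bump (edge leakage is below rounding)
  g <- grid_spec(n_lateral = 20, z_extent = 60, t_end = 52)
  prot <- impulse_protocol(list(c(10, 0)), z_window = c(28, 32),
                           n_lateral = 20)
  wts <- rep(1, 121); wts[c(1, 121)] <- 0.5
  for (res in list(
    simulate_discrete(g, R = 0.4, protocol = prot, reaction_on = FALSE),
    simulate_continuum(g, K = 0.15, protocol = prot, reaction_on = FALSE))) {
    mass <- apply(res$v, 3, function(m) sum(m %*% wts))
    after <- mass[res$times >= 2]          # stimulus has ended; 1000 steps
    expect_lt(max(abs(after - after[1])) / abs(after[1]), 1e-8)
  }
})

test_that("the linear diffusion part converges at second order in dt", {
  runf <- function(dt) {
    gg <- grid_spec(n_lateral = 4, z_extent = 40, dz = 0.5, dt = dt,
                    t_end = 20, snapshot_every = 20)
    simulate_discrete(gg, R = 0.5,
                      protocol = impulse_protocol(list(c(2, 0)),
                                                  n_lateral = 4),
                      reaction_on = FALSE)$v_final
  }
  ref <- runf(0.05 / 16)
  errs <- vapply(c(0.05, 0.025, 0.0125), function(dt)
    max(abs(runf(dt) - ref)), 1)
  expect_gt(errs[1] / errs[2], 3)
  expect_gt(errs[2] / errs[3], 3)
})

test_that("an uncoupled impulse propagates with preserved shape and speed", {
  sp <- cached("pulse_speed", estimate_pulse_speed())
  expect_gt(sp$speed, 0)
  # instantaneous front positions scatter little around the linear fit
  expect_lt(sp$residual_sd / (sp$speed * diff(range(sp$times))), 0.02)

  g1 <- grid_spec(n_lateral = 1, z_extent = 150, t_end = 120)
  run <- simulate_continuum(g1, K = 0,
                            protocol = impulse_protocol(list(c(1, 0)),
                                                        n_lateral = 1))
  amps <- apply(run$v[1, , run$times > 60], 2, max)
  expect_lt(diff(range(amps)) / mean(amps), 0.01)
})

test_that("pulse speed is insensitive to discretization and launch site", {
  sp1 <- cached("pulse_speed", estimate_pulse_speed())
  sp2 <- estimate_pulse_speed(grid = grid_spec(n_lateral = 1, dz = 1,
                                               z_extent = 100, t_end = 10))
  expect_lt(abs(sp2$speed - sp1$speed) / sp1$speed, 0.03)

  # translation symmetry: same arrival time from different launch axons
  g <- grid_spec(n_lateral = 21, z_extent = 80, t_end = 60)
  arrival <- function(axon) {
    res <- simulate_discrete(g, R = 0.8,
                             protocol = impulse_protocol(list(c(axon, 0)),
                                                         n_lateral = 21))
    detect_spikes(res$v[axon, which.min(abs(res$z - 60)), ], res$times)[1]
  }
  expect_lt(abs(arrival(8) - arrival(14)), 1e-6)
})

test_that("invalid protocols and unstable settings raise clear errors", {
  g <- grid_spec(n_lateral = 5, z_extent = 20, t_end = 10)
  expect_error(simulate_discrete(g, 0.5,
                                 protocol = impulse_protocol(list(c(9, 0)))),
               "protocol error")
  expect_error(simulate_discrete(g, 0.5,
                                 protocol = impulse_protocol(list(c(2, 50)))),
               "protocol error")
  expect_error(simulate_discrete(g, 0.5,
                                 protocol = impulse_protocol(list(c(2, 0)),
                                                             z_window = c(10, 30))),
               "protocol error")
  # explosive forcing loses finiteness and names the time step
  expect_error(
    simulate_discrete(g, 0.5,
                      protocol = impulse_protocol(list(c(2, 0)),
                                                  amplitude = 1e4,
                                                  duration = 10)),
    "finiteness")
  # a coupling constant that makes the lateral operator singular
  lat <- ephapse:::lateral_eigen_continuum(5, 1, 0.1)
  K_res <- -1 / min(lat$mu)
  expect_error(simulate_continuum(g, K = K_res,
                                  protocol = impulse_protocol(list(c(2, 0)))),
               "resonant")
})

test_that("z_extent auto-sizing keeps impulses inside the domain", {
  g <- grid_spec(n_lateral = 4, t_end = 60)        # z_extent = NULL
  res <- simulate_discrete(g, R = 0.8,
                           protocol = impulse_protocol(list(c(2, 0)),
                                                       n_lateral = 4))
  expect_gte(max(res$z), 60)                        # at least speed * t_end
  # the impulse front never reaches the far 5% of the domain (only
  # subthreshold diffusive leakage does)
  far <- res$z > 0.95 * max(res$z)
  expect_lt(max(res$v[, far, ]), -0.9)
})
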