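# Engine-level dynamics: initialization, equivalence of the two engines,
# conservation laws, pressure.

test_that("box_length enforces phi = rho pi sigma^3 / 6", {
  expect_equal(box_length(1, pi / 6), 1, tolerance = 1e-14)
  expect_equal(box_length(8, pi / 48), 4, tolerance = 1e-14)
  expect_equal(box_length(4096, 0.46), 16.70579, tolerance = 1e-5)
  expect_error(box_length(100, 0.8), "phi")
  expect_error(box_length(100, 0), "phi")
})

test_that("FCC initialization never overlaps and fails cleanly when too dense", {
  L <- box_length(500, 0.46)
  pos <- init_fcc(500, L, seed = 5)
  expect_identical(nrow(pos), 500L)
  expect_true(all(pos >= 0 & pos < L))
  # brute-force O(N^2) minimum-image overlap scan
  expect_gte(rdfsvd:::.min_pair_distance(pos, L), 1)
  # minimal cell: 4 particles on one FCC cell, spacing = nearest neighbour
  L4 <- 2
  p4 <- init_fcc(4, L4, seed = 1)
  expect_equal(rdfsvd:::.min_pair_distance(p4, L4), L4 / sqrt(2),
               tolerance = 1e-12)
  expect_error(init_fcc(500, 5), "initialization error")
})

test_that("initial velocities are Maxwell-Boltzmann with exact constraints", {
  v <- init_velocities(1000, seed = 3)
  expect_lt(max(abs(colSums(v))), 1e-11)
  expect_equal(sum(v^2) / 2 / 1000, 1.5, tolerance = 1e-13)
  # speed distribution vs the closed-form Maxwell speed density (kT = m = 1)
  v2 <- init_velocities(10000, seed = 4)
  sp <- sqrt(rowSums(v2^2))
  cdf <- function(s) {  # integral of 4 pi (2 pi)^{-3/2} s^2 exp(-s^2/2)
    vapply(s, function(x)
      integrate(function(u) sqrt(2 / pi) * u^2 * exp(-u^2 / 2), 0, x)$value, 0)
  }
  ks <- suppressWarnings(stats::ks.test(sp, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("optimized engine reproduces the brute-force engine exactly", {
  # N <= 32 over >= 10^3 events: heap + cell lists vs fresh all-pairs scans
  spec <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
  N <- 32; phi <- 0.12
  L <- box_length(N, phi)
  st <- system_state(init_fcc(N, L, seed = 11),
                     init_velocities(N, seed = 12), L)
  rb <- run_dmd(st, spec, 12, engine = "brute", record_events = TRUE)
  rc <- run_dmd(st, spec, 12, engine = "cell", record_events = TRUE)
  expect_gt(nrow(rb$events), 1000)
  expect_identical(rb$events, rc$events)
  expect_identical(rb$state$positions, rc$state$positions)
  expect_identical(rb$state$velocities, rc$state$velocities)
})

test_that("free runs conserve energy, momentum, and never overlap the core", {
  spec <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
  N <- 64; phi <- 0.25
  L <- box_length(N, phi)
  st <- system_state(init_fcc(N, L, seed = 21),
                     init_velocities(N, seed = 22), L)
  e0 <- kinetic_energy(st) + potential_energy_state(st, spec)
  res <- run_dmd(st, spec, 100, snapshot_times = seq(10, 100, by = 10),
                 keep_snapshots = TRUE)
  e1 <- kinetic_energy(res$state) + potential_energy_state(res$state, spec)
  expect_lt(abs(e1 - e0) / abs(e0), 1e-10)
  expect_lt(max(abs(total_momentum(res$state))), 1e-9)
  for (snap in res$snapshots)
    expect_gte(rdfsvd:::.min_pair_distance(snap, L), 1 - 1e-9)
})

test_that("production delivers the requested equally spaced snapshots", {
  spec <- make_spec("hs")
  N <- 64; phi <- 0.2
  L <- box_length(N, phi)
  st <- system_state(init_fcc(N, L, seed = 31),
                     init_velocities(N, seed = 32), L)
  cfg <- sim_config(phi, N, seed = 33, snapshot_count = 10L,
                    production_events = 20)
  ke0 <- kinetic_energy(st)
  res <- run_production(st, spec, cfg, event_rate = 5, keep_snapshots = TRUE)
  expect_identical(res$n_snapshots, 10L)
  expect_identical(length(res$snapshots), 10L)
  expect_true(all(diff(res$snapshot_times) > 0))
  expect_equal(diff(res$snapshot_times), rep(diff(res$snapshot_times)[1], 9),
               tolerance = 1e-12)
  # hard spheres: collisions conserve kinetic energy across the whole run
  expect_equal(kinetic_energy(res$state), ke0, tolerance = 1e-10)
})

test_that("virial pressure reduces to the ideal term without events", {
  st <- system_state(rbind(c(1, 1, 1), c(5, 5, 5)),
                     rbind(c(0.1, 0, 0), c(-0.1, 0, 0)), L = 10)
  P <- measure_pressure(0, st, dt = 1)
  rho <- 2 / 1000
  kT <- 2 * kinetic_energy(st) / 6
  expect_equal(P, rho * kT, tolerance = 1e-14)
  expect_error(measure_pressure(0, st, dt = 0), "window")
})

test_that("equilibration reaches the Carnahan-Starling pressure and reports rates", {
  spec <- make_spec("hs")
  N <- 128; phi <- 0.2
  L <- box_length(N, phi)
  st <- system_state(init_fcc(N, L, seed = 41),
                     init_velocities(N, seed = 42), L)
  cfg <- sim_config(phi, N, seed = 43)
  eq <- run_equilibration(st, spec, cfg)
  Z <- eq$pressure / (N / L^3)  # kT = 1
  expect_lt(abs(Z - carnahan_starling_z(phi)) / carnahan_starling_z(phi), 0.05)
  # Enskog collision frequency: nu = 4 sqrt(pi) rho sigma^2 g(sigma)
  res <- run_dmd(eq$state, spec, 20)
  nu <- 2 * sum(res$counts[1:4]) / N / 20
  g_cs <- (1 - phi / 2) / (1 - phi)^3
  nu_enskog <- 4 * sqrt(pi) * (N / L^3) * g_cs
  expect_lt(abs(nu - nu_enskog) / nu_enskog, 0.1)
  # a hopeless event budget raises a non-convergence error
  cfg2 <- sim_config(phi, N, seed = 43, equil_max_windows = 2L)
  expect_error(run_equilibration(st, spec, cfg2), "non-convergence")
})
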