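test_that("config validation and the time-step stability guard", {
  expect_error(langevin_config(temperature = -1), "temperature")
  expect_error(langevin_config(sample_stride = 0), "sample_stride")
  expect_error(langevin_config(n_prod_steps = 5, sample_stride = 10), "sample_stride")
  expect_error(langevin_config(y_floor = 1), "y_floor")
  s <- tiny_promoter()
  big_dt <- langevin_config(dt = 200, n_prod_steps = 10L, sample_stride = 1L,
                            n_replicas = 1L)
  expect_error(simulate_ensemble(s, default_params, big_dt), "stability")
})

test_that("initial velocities are Maxwell-Boltzmann at the target temperature", {
  p <- default_params
  s <- promoter_sequence(strrep("AT", 5000), 1)  # 10^4 sites
  cfg <- langevin_config(temperature = 300)
  set.seed(1)
  st <- initialize_state(s, p, cfg)
  expect_true(all(st$y == 0))
  ke_per_dof <- mean(0.5 * p$mass * st$v^2)
  expect_equal(ke_per_dof, 8.617333e-5 * 300 / 2, tolerance = 0.05)
  # determinism and the T -> 0 limit
  set.seed(7); a <- initialize_state(s, p, cfg)
  set.seed(7); b <- initialize_state(s, p, cfg)
  expect_identical(a, b)
  st0 <- initialize_state(s, p, langevin_config(temperature = 0, friction = 0))
  expect_true(all(st0$v == 0))
})

test_that("langevin_step applies reflecting walls and replays deterministically", {
  p <- default_params
  s <- promoter_sequence("AA", 1)
  cfg <- langevin_config(y_wall = 0.5, y_floor = -0.5)
  # shoot a site at the wall in the deterministic limit
  cfg0 <- langevin_config(temperature = 0, friction = 0, y_wall = 0.5, y_floor = -0.5)
  st <- structure(list(y = c(0.49, 0), v = c(0.05, 0), time = 0), class = "chain_state")
  st1 <- langevin_step(st, s, p, cfg0)
  expect_lte(max(st1$y), 0.5)
  expect_lt(st1$v[1], 0)  # velocity reversed at the wall
  # same RNG seed -> identical stochastic step
  st <- structure(list(y = c(0, 0), v = c(0, 0), time = 0), class = "chain_state")
  set.seed(11); a <- langevin_step(st, s, p, cfg)
  set.seed(11); b <- langevin_step(st, s, p, cfg)
  expect_identical(a, b)
  expect_equal(a$time, cfg$dt / 1000)
})

test_that("simulated displacements respect the walls and frame counting", {
  p <- default_params
  s <- tiny_promoter()
  cfg <- test_scale_config(seed = 3, n_replicas = 2L, n_prod_steps = 500L,
                           n_equil_steps = 100L, y_wall = 3, y_floor = -1)
  ens <- simulate_ensemble(s, p, cfg)
  for (m in ens$replicas) {
    expect_true(all(m >= -1 & m <= 3))
  }
  expect_equal(nrow(ens$replicas[[1]]), 50L)
  expect_equal(ens$sample_dt, 0.1)
  # n_prod_steps == sample_stride -> exactly one stored frame
  cfg1 <- test_scale_config(seed = 3, n_replicas = 1L, n_prod_steps = 10L,
                            n_equil_steps = 0L, sample_stride = 10L)
  expect_equal(nrow(simulate_ensemble(s, p, cfg1)$replicas[[1]]), 1L)
})

test_that("identical master seed and config replay bit-identically", {
  s <- make_sequence(focused_design(2))
  cfg <- test_scale_config(seed = 5, n_replicas = 3L, n_prod_steps = 1000L,
                           n_equil_steps = 500L)
  a <- simulate_ensemble(s, default_params, cfg)
  b <- simulate_ensemble(s, default_params, cfg)
  expect_identical(a$replicas, b$replicas)
  expect_identical(a$replica_seeds, b$replica_seeds)
})

test_that("deterministic limit (gamma = 0, T = 0) conserves energy over 1e5 steps", {
  p <- default_params
  s <- promoter_sequence("AA", 1)
  cfg <- langevin_config(temperature = 0, friction = 0, dt = 10,
                         n_equil_steps = 0L, n_prod_steps = 100000L,
                         sample_stride = 100L, n_replicas = 1L, seed = 1L,
                         store_velocities = TRUE)
  st <- structure(list(y = c(0.01, -0.01), v = c(0, 0), time = 0),
                  class = "chain_state")
  ens <- simulate_ensemble(s, p, cfg, initial_state = st)
  e0 <- total_potential(st$y, s, p)
  pos <- ens$replicas[[1]]; vel <- ens$velocities[[1]]
  energies <- vapply(seq_len(nrow(pos)), function(i) {
    total_potential(pos[i, ], s, p) + 0.5 * p$mass * sum(vel[i, ]^2)
  }, numeric(1))
  expect_lt(max(abs(energies - e0)), 1e-6)
})

test_that("kinetic temperature matches the thermostat within 2 percent", {
  s <- make_sequence(sequence_design(length = 60, background_gc = 0.5, seed = 7))
  cfg <- langevin_config(n_equil_steps = 5000L, n_prod_steps = 10000L,
                         sample_stride = 10L, n_replicas = 16L, seed = 11L,
                         store_velocities = TRUE)  # 1.6 ns aggregate
  ens <- simulate_ensemble(s, default_params, cfg)
  expect_equal(kinetic_temperature(ens), 300, tolerance = 0.02)
  # velocities absent -> diagnostic unavailable
  cfg2 <- test_scale_config(seed = 1, n_replicas = 1L, n_prod_steps = 100L,
                            n_equil_steps = 0L)
  expect_error(kinetic_temperature(simulate_ensemble(tiny_promoter(),
                                                     default_params, cfg2)),
               "store_velocities")
})

test_that("quadrature oracle: boundary thresholds and monotone behaviour", {
  p <- default_params
  expect_equal(equilibrium_opening_probability_oracle("AT", p, 300, -2, -2, 20), 1)
  expect_equal(equilibrium_opening_probability_oracle("AT", p, 300, 20, -2, 20), 0)
  probs <- vapply(c(0.5, 1.0, 1.5), function(th)
    equilibrium_opening_probability_oracle("AT", p, 300, th, -2, 20), numeric(1))
  expect_true(all(diff(probs) < 0))  # stricter threshold, lower probability
  # GC opens less than AT at the same threshold
  expect_lt(equilibrium_opening_probability_oracle("GC", p, 300, 1.0, -2, 20),
            equilibrium_opening_probability_oracle("AT", p, 300, 1.0, -2, 20))
  expect_error(equilibrium_opening_probability_oracle("AT", p, 300, 30, -2, 20),
               "threshold")
})

test_that("single-site Langevin occupancy agrees with the Boltzmann quadrature", {
  p <- default_params
  # friction 0.5/ps: box-crossing diffusion fast enough that 2 ns + 4 ns
  # runs decorrelate well while staying cheap
  cfg <- langevin_config(friction = 0.5, n_equil_steps = 200000L,
                         n_prod_steps = 400000L, sample_stride = 100L,
                         n_replicas = 48L, seed = 42L)
  ens <- simulate_single_site("AT", p, cfg)
  for (th in c(0.5, 1.0, 1.5)) {
    occ <- site_occupancy(ens, th)
    se <- stats::sd(occ) / sqrt(length(occ))
    oracle <- equilibrium_opening_probability_oracle("AT", p, 300, th, -2, 20)
    expect_lt(abs(mean(occ) - oracle), 3 * se)
  }
})

test_that("AT homopolymer opens more than GC at the same conditions", {
  p <- default_params
  cfg <- test_scale_config(seed = 9, n_replicas = 8L)
  at <- simulate_ensemble(promoter_sequence(strrep("A", 20), 10), p, cfg)
  gc <- simulate_ensemble(promoter_sequence(strrep("G", 20), 10), p, cfg)
  expect_gt(mean(do.call(rbind, at$replicas)), mean(do.call(rbind, gc$replicas)))
})

test_that("occupancy above a fixed threshold is non-decreasing in temperature", {
  p <- default_params
  occs <- vapply(c(250, 300, 350), function(Tk) {
    cfg <- langevin_config(temperature = Tk, n_equil_steps = 20000L,
                           n_prod_steps = 40000L, sample_stride = 20L,
                           n_replicas = 16L, seed = 5L)
    mean(site_occupancy(simulate_single_site("GC", p, cfg), 0.5))
  }, numeric(1))
  expect_true(all(diff(occs) > 0))
})
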