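#' Langevin thermostat / integrator configuration
#'
#' Settings for constant-temperature Langevin molecular dynamics of the
#' EPBD chain: a BAOAB-discretized Langevin equation (stochastic
#' velocity-Verlet family; exact Ornstein-Uhlenbeck velocity substep, so
#' the fluctuation-dissipation balance holds at any dt, and the gamma = 0,
#' T = 0 limit is plain velocity Verlet), with reflecting walls bounding
#' the pair-stretch coordinate. The walls make the Morse partition
#' function finite; the equilibrium-quadrature oracle integrates over the
#' same interval so molecular dynamics and quadrature are directly
#' comparable.
#'
#' Defaults are publication scale (1 ns production x 100 replicas);
#' [test_scale_config()] gives the small profile used throughout the test
#' suite (50 ps x 20 replicas).
#'
#' @param temperature Thermostat temperature, K.
#' @param friction Langevin friction gamma, 1/ps. The default 5/ps is of
#'   the order of the Morse well frequency (Kramers turnover), where
#'   barrier-crossing (base-pair opening) events are sampled most
#'   efficiently and kinetic energy equilibrates within a fraction of a
#'   picosecond; it is also the damping scale expected for a base pair
#'   moving against water.
#' @param dt Integration time step, fs.
#' @param n_equil_steps Discarded equilibration steps.
#' @param n_prod_steps Production steps.
#' @param sample_stride Steps between stored frames.
#' @param n_replicas Independent replicas (each gets a child seed derived
#'   from `seed` and the replica index only, so results are independent
#'   of execution order).
#' @param seed Master seed (integer).
#' @param y_floor,y_wall Reflecting walls, Angstrom (`y_floor < 0 < y_wall`).
#' @param store_velocities Keep sampled velocities (needed by
#'   [kinetic_temperature()]).
#' @return A `langevin_config` object.
#' @export
langevin_config <- function(temperature = 300,
                            friction = 5,
                            dt = 10,
                            n_equil_steps = 5000L,
                            n_prod_steps = 100000L,
                            sample_stride = 10L,
                            n_replicas = 100L,
                            seed = 1L,
                            y_floor = -2,
                            y_wall = 20,
                            store_velocities = FALSE) {
  # temperature = 0 and friction = 0 are admitted as the deterministic
  # (velocity Verlet) limit used for energy-conservation checks
  stopifnot(temperature >= 0, friction >= 0, dt > 0)
  n_equil_steps <- as.integer(n_equil_steps)
  n_prod_steps <- as.integer(n_prod_steps)
  sample_stride <- as.integer(sample_stride)
  n_replicas <- as.integer(n_replicas)
  if (n_equil_steps < 0L) stop("n_equil_steps must be >= 0")
  if (sample_stride < 1L || n_prod_steps < sample_stride) {
    stop("require n_prod_steps >= sample_stride >= 1")
  }
  if (n_replicas < 1L) stop("n_replicas must be >= 1")
  if (!(y_floor < 0 && 0 < y_wall)) stop("require y_floor < 0 < y_wall")
  structure(
    list(temperature = temperature, friction = friction, dt = dt,
         n_equil_steps = n_equil_steps, n_prod_steps = n_prod_steps,
         sample_stride = sample_stride, n_replicas = n_replicas,
         seed = as.integer(seed), y_floor = y_floor, y_wall = y_wall,
         store_velocities = isTRUE(store_velocities)),
    class = "langevin_config"
  )
}

#' Test-scale Langevin configuration
#'
#' 50 ps equilibration + 50 ps production, 20 replicas — the small
#' profile used for fast, statistically coarse runs (tests, smoke
#' checks). Any field can be overridden.
#'
#' @param ... Overrides passed to [langevin_config()].
#' @export
test_scale_config <- function(...) {
  args <- list(n_equil_steps = 5000L, n_prod_steps = 5000L,
               sample_stride = 10L, n_replicas = 20L)
  override <- list(...)
  args[names(override)] <- override
  do.call(langevin_config, args)
}

# Time-step stability guard: dt * a_max * sqrt(kB T / m) must stay well
# below the fastest Morse curvature scale (all in internal units).
check_stability <- function(config, params) {
  dt_int <- config$dt / T0_FS
  a_max <- max(params$a)
  guard <- dt_int * a_max * sqrt(KB_EV * config$temperature / params$mass)
  if (guard >= 0.1) {
    stop(sprintf("dt = %g fs is too large for these parameters (stability guard %.3f >= 0.1); reduce dt",
                 config$dt, guard))
  }
  invisible(guard)
}

# Child seeds for all replicas: the i-th draw (without replacement) from
# the master-seeded stream. Depends only on (master seed, replica index);
# drawn rather than arithmetically spaced so the child streams carry no
# structural correlation. Restores the caller's RNG state.
derive_child_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

#' Draw an initial chain state
#'
#' Closed duplex (all pair stretches at the Morse minimum y = 0) with
#' Maxwell-Boltzmann velocities at the thermostat temperature. Uses R's
#' RNG stream: call `set.seed()` first for reproducibility.
#'
#' @param seq A [promoter_sequence].
#' @param params An [epbd_parameters] object.
#' @param config A [langevin_config].
#' @return A `chain_state` list with fields `y` (Angstrom), `v`
#'   (Angstrom per internal time unit) and `time` (ps).
#' @export
initialize_state <- function(seq, params, config) {
  stopifnot(inherits(seq, "promoter_sequence"))
  n <- nchar(seq$bases)
  v_scale <- sqrt(KB_EV * config$temperature / params$mass)
  structure(list(y = rep(0, n), v = stats::rnorm(n, sd = v_scale), time = 0),
            class = "chain_state")
}

#' Advance a chain state by one Langevin (BAOAB) step
#'
#' Reference single-step implementation in R, mirroring the compiled
#' integrator: half kick, half drift (with wall reflection), exact
#' Ornstein-Uhlenbeck velocity refresh, half drift, half kick. With
#' `friction -> 0` and `temperature -> 0` this is one velocity-Verlet
#' step.
#'
#' @param state A `chain_state` (see [initialize_state()]).
#' @inheritParams initialize_state
#' @return The advanced `chain_state` (`time` advanced by dt).
#' @export
langevin_step <- function(state, seq, params, config) {
  n <- nchar(seq$bases)
  stopifnot(length(state$y) == n, length(state$v) == n)
  dt <- config$dt / T0_FS
  gamma <- config$friction * T0_PS
  c1 <- exp(-gamma * dt)
  c2 <- sqrt(max(0, 1 - c1^2)) * sqrt(KB_EV * config$temperature / params$mass)
  m <- params$mass
  y <- state$y; v <- state$v

  v <- v + (dt / (2 * m)) * total_force(y, seq, params)
  y <- y + (dt / 2) * v
  refl <- reflect_walls(y, v, config$y_floor, config$y_wall)
  y <- refl$y; v <- refl$v
  if (c2 > 0) v <- c1 * v + c2 * stats::rnorm(n) else v <- c1 * v
  y <- y + (dt / 2) * v
  refl <- reflect_walls(y, v, config$y_floor, config$y_wall)
  y <- refl$y; v <- refl$v
  v <- v + (dt / (2 * m)) * total_force(y, seq, params)

  if (any(!is.finite(y)) || any(!is.finite(v))) {
    stop("non-finite state after Langevin step: the integration is unstable, reduce dt")
  }
  structure(list(y = y, v = v, time = state$time + config$dt / 1000),
            class = "chain_state")
}

reflect_walls <- function(y, v, y_floor, y_wall) {
  over <- y > y_wall
  y[over] <- 2 * y_wall - y[over]; v[over] <- -v[over]
  under <- y < y_floor
  y[under] <- 2 * y_floor - y[under]; v[under] <- -v[under]
  list(y = y, v = v)
}

run_replica <- function(n, D, a, ks, params, config, seed, initial_state = NULL) {
  set.seed(seed)
  if (is.null(initial_state)) {
    y0 <- rep(0, n)
    v_scale <- sqrt(KB_EV * config$temperature / params$mass)
    v0 <- if (v_scale > 0) stats::rnorm(n, sd = v_scale) else rep(0, n)
  } else {
    y0 <- initial_state$y
    v0 <- initial_state$v
  }
  dt <- config$dt / T0_FS
  gamma <- config$friction * T0_PS
  cpp_simulate(y0, v0, D, a, ks, params$rho, params$beta, params$mass,
               dt, exp(-gamma * dt), KB_EV * config$temperature,
               config$n_equil_steps, config$n_prod_steps, config$sample_stride,
               config$y_floor, config$y_wall, config$store_velocities)
}

#' Simulate an ensemble of Langevin trajectories
#'
#' Runs `n_replicas` independent trajectories of the EPBD chain for a
#' promoter sequence. Each replica equilibrates for `n_equil_steps`, then
#' stores every `sample_stride`-th production frame. Replica i is seeded
#' by a deterministic child of `(config$seed, i)` so the ensemble is
#' bit-reproducible and independent of evaluation order.
#'
#' @inheritParams initialize_state
#' @param initial_state Optional `chain_state` used as the starting point
#'   of every replica instead of the default (closed duplex,
#'   Maxwell-Boltzmann velocities). Mainly for deterministic-limit
#'   checks.
#' @return A `trajectory_ensemble`: list with `replicas` (each a frames x
#'   N matrix of pair stretches, Angstrom), optional `velocities`,
#'   `sample_dt` (ps between stored frames), and full provenance
#'   (`seq`, `config`, `params`, `replica_seeds`).
#' @export
simulate_ensemble <- function(seq, params = epbd_parameters(),
                              config = langevin_config(),
                              initial_state = NULL) {
  stopifnot(inherits(seq, "promoter_sequence"),
            inherits(params, "epbd_parameters"),
            inherits(config, "langevin_config"))
  check_stability(config, params)
  n <- nchar(seq$bases)
  sc <- site_constants(seq, params)
  ks <- step_constants(seq, params)
  seeds <- derive_child_seeds(config$seed, config$n_replicas)
  replicas <- vector("list", config$n_replicas)
  velocities <- if (config$store_velocities) vector("list", config$n_replicas) else NULL
  if (!is.null(initial_state)) {
    stopifnot(length(initial_state$y) == n, length(initial_state$v) == n)
  }
  for (r in seq_len(config$n_replicas)) {
    res <- tryCatch(
      run_replica(n, sc$D, sc$a, ks, params, config, seeds[[r]], initial_state),
      error = function(e) stop("replica ", r, ": ", conditionMessage(e))
    )
    replicas[[r]] <- res$positions
    if (config$store_velocities) velocities[[r]] <- res$velocities
  }
  structure(
    list(replicas = replicas, velocities = velocities,
         sample_dt = config$dt * config$sample_stride / 1000,
         seq = seq, config = config, params = params, replica_seeds = seeds),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: '%s' (%d bp), %d replicas x %d frames, sample_dt = %g ps, T = %g K\n",
              x$seq$name, nchar(x$seq$bases), length(x$replicas),
              nrow(x$replicas[[1L]]), x$sample_dt, x$config$temperature))
  invisible(x)
}

#' Kinetic temperature of an ensemble
#'
#' Equipartition estimate `<m v^2> / k_B` averaged over all stored
#' frames, sites and replicas — the standard thermostat diagnostic.
#' Requires the ensemble to have been run with
#' `store_velocities = TRUE`.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @return Temperature estimate, K.
#' @export
kinetic_temperature <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  if (is.null(ensemble$velocities)) {
    stop("kinetic temperature unavailable: the ensemble was run without store_velocities = TRUE")
  }
  m <- ensemble$params$mass
  msv <- mean(vapply(ensemble$velocities, function(v) mean(v^2), numeric(1L)))
  m * msv / KB_EV
}

#' Simulate a single uncoupled base pair
#'
#' One-site Langevin dynamics in the bare Morse potential (no stacking
#' partner), matching the setting of
#' [equilibrium_opening_probability_oracle()]: the sampled occupancy
#' above a threshold should agree with the quadrature of the Boltzmann
#' factor over the same walled interval.
#'
#' @param base_class `"AT"` or `"GC"`.
#' @inheritParams initialize_state
#' @return A `trajectory_ensemble` with 1-column replica matrices.
#' @export
simulate_single_site <- function(base_class, params = epbd_parameters(),
                                 config = langevin_config()) {
  if (!base_class %in% c("AT", "GC")) stop("unknown base class: ", base_class)
  check_stability(config, params)
  D <- params$D[[base_class]]; a <- params$a[[base_class]]
  seeds <- derive_child_seeds(config$seed, config$n_replicas)
  replicas <- vector("list", config$n_replicas)
  velocities <- if (config$store_velocities) vector("list", config$n_replicas) else NULL
  for (r in seq_len(config$n_replicas)) {
    res <- run_replica(1L, D, a, numeric(0), params, config, seeds[[r]])
    replicas[[r]] <- res$positions
    if (config$store_velocities) velocities[[r]] <- res$velocities
  }
  seq_stub <- structure(
    list(name = paste0("single-", base_class), bases = base_class, tss_index = 1L),
    class = "promoter_sequence"
  )
  structure(
    list(replicas = replicas, velocities = velocities,
         sample_dt = config$dt * config$sample_stride / 1000,
         seq = seq_stub, config = config, params = params, replica_seeds = seeds),
    class = "trajectory_ensemble"
  )
}

#' Equilibrium opening probability of one base pair by quadrature
#'
#' Independent brute-force oracle for validating the Langevin sampler:
#' the canonical probability that a single uncoupled base pair, confined
#' between reflecting walls, is open beyond a threshold,
#' `P = integral(threshold..y_wall) exp(-V/kT) dy / integral(y_floor..y_wall) exp(-V/kT) dy`
#' with `V` the Morse on-site potential, computed by adaptive quadrature
#' (relative tolerance 1e-8).
#'
#' @param base_class `"AT"` or `"GC"`.
#' @param params An [epbd_parameters] object.
#' @param temperature Temperature, K.
#' @param threshold Opening threshold, Angstrom (within `[y_floor, y_wall]`).
#' @param y_floor,y_wall Reflecting walls shared with the dynamics, Angstrom.
#' @return Probability in `[0, 1]`.
#' @export
equilibrium_opening_probability_oracle <- function(base_class,
                                                   params = epbd_parameters(),
                                                   temperature = 300,
                                                   threshold = 1.0,
                                                   y_floor = -2,
                                                   y_wall = 20) {
  if (!base_class %in% c("AT", "GC")) stop("unknown base class: ", base_class)
  if (threshold < y_floor || threshold > y_wall) {
    stop("threshold must lie within [y_floor, y_wall]")
  }
  if (threshold == y_floor) return(1.0)
  if (threshold == y_wall) return(0.0)
  kT <- KB_EV * temperature
  D <- params$D[[base_class]]; a <- params$a[[base_class]]
  w <- function(y) exp(-D * (exp(-a * y) - 1)^2 / kT)
  quad <- function(lo, hi) {
    r <- stats::integrate(w, lo, hi, rel.tol = 1e-8, abs.tol = 0)
    if (r$message != "OK") stop("quadrature failed: ", r$message)
    r$value
  }
  # split integration at y = 0 so the adaptive rule resolves the narrow well
  num <- if (threshold < 0) quad(threshold, 0) + quad(0, y_wall) else quad(threshold, y_wall)
  num / (quad(y_floor, 0) + quad(0, y_wall))
}

#' Occupancy above a threshold, per replica
#'
#' Fraction of stored frames in which a given site's stretch is at or
#' above `threshold`, returned per replica (so the spread across
#' independent replicas yields a standard error).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param threshold Opening threshold, Angstrom.
#' @param site 1-based site index (default 1; the only site for
#'   single-site ensembles).
#' @return Numeric vector, one occupancy per replica.
#' @export
site_occupancy <- function(ensemble, threshold, site = 1L) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  vapply(ensemble$replicas, function(m) mean(m[, site] >= threshold), numeric(1L))
}
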