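#' @useDynLib rdfsvd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils modifyList read.table write.table
NULL

#' Periodic box length for a target packing fraction
#'
#' The packing fraction is phi = rho * pi * sigma^3 / 6 with number density
#' rho = N / L^3, so L = (N pi sigma^3 / (6 phi))^(1/3).
#'
#' @param N particle count.
#' @param phi packing fraction, in (0, 0.74).
#' @param sigma core diameter.
#' @return box edge length.
#' @export
box_length <- function(N, phi, sigma = 1) {
  stopifnot(N >= 1)
  if (!is.numeric(phi) || phi <= 0 || phi >= 0.74)
    stop("'phi' must lie in (0, 0.74)")
  (N * pi * sigma^3 / (6 * phi))^(1 / 3)
}

#' Place particles on randomly chosen FCC lattice sites
#'
#' Builds the smallest cubic FCC lattice with at least `N` sites in a box of
#' edge `L` and occupies `N` randomly selected sites, so that no pair
#' overlaps at any density where the nearest-neighbour spacing exceeds
#' `sigma`.
#'
#' @param N particle count.
#' @param L box edge length.
#' @param sigma core diameter (overlap guard).
#' @param seed integer seed for the random site selection.
#' @return an `N x 3` matrix of positions in `[0, L)`.
#' @export
init_fcc <- function(N, L, sigma = 1, seed = 1L) {
  stopifnot(N >= 1, L > 0)
  ncell <- max(1L, ceiling((N / 4)^(1 / 3)))
  while (4 * ncell^3 < N) ncell <- ncell + 1L
  a <- L / ncell
  if (a / sqrt(2) < sigma)
    stop("initialization error: FCC nearest-neighbour spacing below sigma ",
         "(packing fraction too high for N)")
  base <- matrix(c(0, 0, 0, 0, .5, .5, .5, 0, .5, .5, .5, 0),
                 ncol = 3, byrow = TRUE)
  idx <- as.matrix(expand.grid(x = 0:(ncell - 1), y = 0:(ncell - 1),
                               z = 0:(ncell - 1)))
  sites <- do.call(rbind, lapply(seq_len(4), function(k)
    sweep(idx, 2, base[k, ], "+")))
  sites <- sites * a
  if (N > nrow(sites))
    stop("initialization error: not enough lattice sites")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pick <- sample.int(nrow(sites), N)
  pos <- sites[pick, , drop = FALSE]
  pos %% L
}

#' Maxwell-Boltzmann velocities with exact constraints
#'
#' Draws velocities at temperature `kT`, removes the centre-of-mass drift and
#' rescales so the mean kinetic energy per particle is exactly `1.5 * kT`.
#'
#' @param N particle count (>= 2).
#' @param kT temperature in reduced units.
#' @param seed integer seed.
#' @return an `N x 3` matrix of velocities.
#' @export
init_velocities <- function(N, kT = 1, seed = 1L) {
  stopifnot(N >= 2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  v <- matrix(rnorm(3 * N, sd = sqrt(kT)), ncol = 3)
  v <- sweep(v, 2, colMeans(v))
  ke <- sum(v^2) / 2
  v * sqrt(1.5 * N * kT / ke)
}

# seed handling that restores the caller's RNG state
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Construct a system state
#'
#' @param positions `N x 3` matrix, wrapped into `[0, L)`.
#' @param velocities `N x 3` matrix.
#' @param L box edge length.
#' @param time current simulation time.
#' @return an object of class `system_state`.
#' @export
system_state <- function(positions, velocities, L, time = 0) {
  stopifnot(is.matrix(positions), is.matrix(velocities),
            ncol(positions) == 3, ncol(velocities) == 3,
            nrow(positions) == nrow(velocities), L > 0)
  structure(list(positions = positions %% L, velocities = velocities,
                 L = L, time = time, N = nrow(positions)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: N = %d, L = %.4f, t = %.4f, KE/N = %.4f\n",
              x$N, x$L, x$time, kinetic_energy(x) / x$N))
  invisible(x)
}

#' Kinetic and potential energy of a state
#'
#' @param state a [system_state()].
#' @param spec a [make_spec()] potential (for `potential_energy_state`).
#' @return energy in kT units.
#' @export
kinetic_energy <- function(state) sum(state$velocities^2) / 2

#' @rdname kinetic_energy
#' @export
potential_energy_state <- function(state, spec) {
  rd <- spec_radii(spec)
  .potential_energy(state$positions, state$L, rd$radii, rd$depths)
}

#' @rdname kinetic_energy
#' @export
total_momentum <- function(state) colSums(state$velocities)

spec_radii <- function(spec) {
  list(radii = spec$sigma * c(1, spec$boundaries), depths = spec$depths)
}

#' Simulation configuration
#'
#' @param phi packing fraction.
#' @param N particle count.
#' @param seed master seed; fans out to named substreams (placement,
#'   velocities, thermostat).
#' @param snapshot_count production snapshots at equal time intervals.
#' @param equil_window time length of one pressure window during
#'   equilibration.
#' @param equil_tol relative spread of the last 5 window pressures that
#'   counts as steady.
#' @param equil_max_windows cap on windows per phase.
#' @param equil_min_events minimum pair events per particle a phase must
#'   accumulate before the steadiness criterion applies (decorrelation is
#'   measured in collisions, so dilute systems are not declared steady on
#'   pressure noise alone).
#' @param thermostat `"rescale"` (velocity rescale at window boundaries
#'   during equilibration phase 2; production runs free, NVE),
#'   `"andersen"` (additionally, during production a random subset of
#'   particles has velocities re-drawn from the Maxwell-Boltzmann
#'   distribution between snapshot segments, sampling the canonical
#'   ensemble at kT = 1), or `"none"`.
#' @param production_events mean number of pair events per particle the
#'   production run should span; sets the production time from the measured
#'   event rate.
#' @param max_events safety cap on processed events per engine call.
#' @param engine `"auto"`, `"cell"` or `"brute"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(phi, N, seed = 1L, snapshot_count = 200L,
                       equil_window = 2, equil_tol = 1e-2,
                       equil_max_windows = 200L, equil_min_events = 30,
                       thermostat = "rescale",
                       production_events = 100, max_events = 5e8,
                       engine = "auto") {
  if (!is.numeric(phi) || phi <= 0 || phi >= 0.74)
    stop("'phi' must lie in (0, 0.74)")
  stopifnot(snapshot_count >= 1)
  structure(list(phi = phi, N = as.integer(N), seed = as.integer(seed),
                 snapshot_count = as.integer(snapshot_count),
                 equil_window = equil_window, equil_tol = equil_tol,
                 equil_max_windows = as.integer(equil_max_windows),
                 equil_min_events = equil_min_events,
                 thermostat = thermostat,
                 production_events = production_events,
                 max_events = max_events, engine = engine),
            class = "sim_config")
}

# derived, reproducible sub-seeds for the named random substreams
sub_seed <- function(seed, stream) {
  offs <- c(placement = 101, velocities = 211, thermostat = 307,
            sweep = 401)
  as.integer((as.numeric(seed) * 7919 + offs[[stream]]) %% 2147483011)
}

choose_engine <- function(engine, L, spec, N) {
  rng <- potential_range(spec)
  if (engine == "brute") return(FALSE)
  ncell <- floor(L / rng)
  if (engine == "cell") {
    if (ncell < 3) stop("cell engine requires at least 3 cells per side")
    return(TRUE)
  }
  ncell >= 3 && N >= 16
}

#' Run the event-driven dynamics for a time interval
#'
#' Low-level wrapper around the compiled engine.  Propagates the state
#' exactly from event to event; optionally collects snapshots, accumulates a
#' pair-distance histogram, applies velocity rescaling at given times, and
#' records the applied event log.
#'
#' @param state a [system_state()].
#' @param spec a [make_spec()] potential.
#' @param t_dur duration to advance.
#' @param snapshot_times absolute times (within the interval) at which to
#'   sample; default none.
#' @param rescale_times absolute times at which to rescale velocities to
#'   `rescale_kT`.
#' @param rescale_kT thermostat temperature.
#' @param engine `"auto"`, `"cell"` or `"brute"`.
#' @param rdf_grid optional [radial_grid()]; when given, pair histograms are
#'   accumulated over the snapshots.
#' @param keep_snapshots return the snapshot positions as a list.
#' @param record_events return the applied pair-event log.
#' @param max_events safety cap.
#' @return list with the advanced `state`, `virial` sum, event `counts`, and
#'   optionally `rdf_counts`, `snapshots`, `events`.
#' @export
run_dmd <- function(state, spec, t_dur, snapshot_times = numeric(0),
                    rescale_times = numeric(0), rescale_kT = 1,
                    engine = "auto", rdf_grid = NULL,
                    keep_snapshots = FALSE, record_events = FALSE,
                    max_events = 5e8) {
  stopifnot(inherits(state, "system_state"), inherits(spec, "potential_spec"),
            t_dur >= 0)
  rd <- spec_radii(spec)
  cells <- choose_engine(engine, state$L, spec, state$N)
  nb <- 0L; rmax <- 0
  if (!is.null(rdf_grid)) {
    if (rdf_grid$r_max > state$L / 2)
      stop("configuration error: r_max exceeds L/2")
    nb <- rdf_grid$m; rmax <- rdf_grid$r_max
  }
  res <- .dmd_run(state$positions, state$velocities, state$L,
                  rd$radii, rd$depths, state$time, state$time + t_dur,
                  as.numeric(snapshot_times), as.numeric(rescale_times),
                  rescale_kT, cells, max_events, record_events,
                  nb, rmax, keep_snapshots)
  out <- list(
    state = system_state(res$positions, res$velocities, state$L, res$time),
    virial = res$virial, counts = res$counts,
    n_snapshots = res$n_snapshots)
  if (!is.null(res$rdf_counts)) out$rdf_counts <- res$rdf_counts
  if (!is.null(res$snapshots)) out$snapshots <- res$snapshots
  if (!is.null(res$events)) {
    ev <- as.data.frame(res$events)
    ev$type <- c("core_collision", "shell_cross_in", "shell_cross_out",
                 "bounce")[ev$type + 1]
    out$events <- ev
  }
  out
}

#' Predict the next event for an isolated pair
#'
#' Exact earliest crossing of any potential boundary for two free-flying
#' particles under the minimum-image convention.
#'
#' @param r1,v1,r2,v2 position and velocity 3-vectors.
#' @param spec a [make_spec()] potential.
#' @param L box edge (use a large value for an effectively open system).
#' @return list with `time`, `type` (`"core_collision"`, `"shell_cross_in"`,
#'   `"shell_cross_out"` or `"none"`) and `boundary` radius.
#' @export
predict_pair_event <- function(r1, v1, r2, v2, spec, L = 1e6) {
  rd <- spec_radii(spec)
  .dmd_predict_pair(as.numeric(r1), as.numeric(v1), as.numeric(r2),
                    as.numeric(v2), L, rd$radii)
}

#' Resolve an event at a potential boundary
#'
#' Applies the exact equal-mass impulse for a core collision, a shell
#' capture/entry, or an attempted escape (which reflects into a bounce when
#' the radial kinetic energy cannot pay the potential step).
#'
#' @param dr separation vector `r1 - r2` at the boundary.
#' @param v1,v2 velocities.
#' @param boundary boundary radius (must match one of the spec's).
#' @param kind `"core_collision"`, `"shell_cross_in"` or `"shell_cross_out"`.
#' @param spec a [make_spec()] potential.
#' @return list with updated `v1`, `v2`, the applied `outcome` and the
#'   virial contribution.
#' @export
resolve_event <- function(dr, v1, v2, boundary, kind, spec) {
  rd <- spec_radii(spec)
  bidx <- which(abs(rd$radii - boundary) < 1e-9) - 1L
  if (length(bidx) != 1L)
    stop("event boundary does not match the potential")
  if (kind == "core_collision" && bidx != 0L)
    stop("core collision must occur at sigma")
  if (kind != "core_collision" && bidx == 0L)
    stop("shell crossing cannot occur at sigma")
  .dmd_resolve_pair(as.numeric(dr), as.numeric(v1), as.numeric(v2),
                    bidx, kind, rd$radii, rd$depths)
}

#' Virial pressure over a time window
#'
#' P = rho kT + W / (3 V dt) with W the accumulated sum of m (dv_i . r_ij)
#' over the resolved pair events in the window.
#'
#' @param virial accumulated virial sum W.
#' @param state a [system_state()] (provides N, V and the kinetic
#'   temperature).
#' @param dt window length (> 0).
#' @param kT temperature; default measured from the state.
#' @return pressure in reduced units.
#' @export
measure_pressure <- function(virial, state, dt, kT = NULL) {
  if (dt <= 0) stop("zero-length pressure window")
  V <- state$L^3
  rho <- state$N / V
  if (is.null(kT)) kT <- 2 * kinetic_energy(state) / (3 * state$N)
  rho * kT + virial / (3 * V * dt)
}

#' Two-phase equilibration to a steady pressure
#'
#' Phase 1 strips the shells (pure hard spheres) to decorrelate the lattice
#' start; phase 2 restores the potential.  Each phase runs in windows of
#' `config$equil_window` time units and ends once the last five window
#' pressures have a relative spread below `config$equil_tol`.  During phase 2
#' a velocity-rescale thermostat holds kT = 1 at window boundaries (unless
#' `thermostat = "none"`).
#'
#' @param state a [system_state()].
#' @param spec a [make_spec()] potential.
#' @param config a [sim_config()].
#' @return list with the equilibrated `state`, the measured pair-event rate
#'   per particle per time (`event_rate`), the final window pressure and the
#'   per-phase window pressure traces.
#' @export
run_equilibration <- function(state, spec, config) {
  hs <- make_spec("hs", sigma = spec$sigma)
  phases <- if (length(spec$boundaries) == 0L) list(hs) else list(hs, spec)
  traces <- list()
  rate <- NA_real_
  P_last <- NA_real_
  for (ph in seq_along(phases)) {
    sp <- phases[[ph]]
    thermo <- ph == 2L && config$thermostat %in% c("rescale", "andersen")
    win <- numeric(0)
    all_win <- numeric(0)
    wlen <- config$equil_window
    total <- 0L
    phase_events <- 0
    repeat {
      t1 <- state$time + wlen
      res <- run_dmd(state, sp, wlen,
                     rescale_times = if (thermo) t1 else numeric(0),
                     rescale_kT = 1, engine = config$engine,
                     max_events = config$max_events)
      state <- res$state
      P <- measure_pressure(res$virial, state, wlen)
      win <- c(win, P)
      all_win <- c(all_win, P)
      total <- total + 1L
      nev <- sum(res$counts[c("core", "capture", "escape", "bounce")])
      rate <- nev / state$N / wlen
      phase_events <- phase_events + nev
      nw <- length(win)
      # spread scale: |P| with the ideal-gas pressure as a floor, so the
      # criterion stays attainable when attraction cancels most of P
      pscale <- max(abs(mean(win)), state$N / state$L^3)
      if (nw >= 5 && phase_events / state$N >= config$equil_min_events) {
        last5 <- win[(nw - 4):nw]
        if ((max(last5) - min(last5)) < config$equil_tol * pscale)
          break
        # plateau test: once the drift between the two most recent blocks of
        # five windows is indistinguishable from the window-to-window noise,
        # the pressure is steady at the resolution this schedule can see
        if (nw >= 10) {
          b1 <- mean(win[(nw - 9):(nw - 5)])
          b2 <- mean(last5)
          noise <- stats::sd(win[(nw - 9):nw]) * sqrt(2 / 5)
          if (abs(b2 - b1) < max(config$equil_tol * pscale, 1.5 * noise))
            break
        }
      }
      # windowed virial noise can exceed the steadiness tolerance: if 10
      # windows at this length have not settled, average over longer ones
      # (growth capped at 16x the configured window)
      if (nw >= 10L && wlen < 16 * config$equil_window) {
        wlen <- 2 * wlen
        win <- numeric(0)
      }
      if (total >= config$equil_max_windows)
        stop("non-convergence: pressure not steady after ",
             config$equil_max_windows, " windows (last pressures: ",
             paste(signif(utils::tail(all_win, 5), 6), collapse = ", "), ")")
    }
    traces[[ph]] <- all_win
    P_last <- mean(utils::tail(win, 5))
  }
  list(state = state, event_rate = rate, pressure = P_last,
       pressure_windows = traces)
}

#' Production run: snapshots at equal time intervals
#'
#' The production length is chosen so an average particle experiences at
#' least `config$production_events` pair events (using the event rate
#' measured during equilibration); `config$snapshot_count` snapshots are
#' taken at equal time intervals.  The run is free (NVE): energy and momentum
#' are conserved to machine precision.
#'
#' @param state an equilibrated [system_state()].
#' @param spec a [make_spec()] potential.
#' @param config a [sim_config()].
#' @param event_rate pair events per particle per unit time (from
#'   [run_equilibration()]); a conservative default is used when missing.
#' @param rdf_grid optional [radial_grid()] for in-flight histogram
#'   accumulation.
#' @param keep_snapshots return the snapshot positions.
#' @return list with final `state`, `snapshot_times`, `virial`, `counts`,
#'   and `rdf_counts`/`snapshots` when requested.
#' @export
run_production <- function(state, spec, config, event_rate = NULL,
                           rdf_grid = NULL, keep_snapshots = FALSE) {
  if (is.null(event_rate) || !is.finite(event_rate) || event_rate <= 0)
    event_rate <- 1
  t_total <- max(config$production_events / event_rate,
                 config$snapshot_count * 0.05)
  dt <- t_total / config$snapshot_count
  times <- state$time + dt * seq_len(config$snapshot_count)
  if (!identical(config$thermostat, "andersen")) {
    res <- run_dmd(state, spec, t_total, snapshot_times = times,
                   engine = config$engine, rdf_grid = rdf_grid,
                   keep_snapshots = keep_snapshots,
                   max_events = config$max_events)
    res$snapshot_times <- times
    return(res)
  }
  # Andersen-style thermostat: between snapshot segments, re-draw a random
  # subset of velocities from the Maxwell-Boltzmann distribution at kT = 1.
  # The configurational distribution sampled is canonical; within each
  # segment the dynamics remain exact NVE.
  old <- local_seed(sub_seed(config$seed, "thermostat"))
  on.exit(restore_seed(old))
  n_seg <- min(50L, config$snapshot_count)
  seg <- split(times, ceiling(seq_along(times) / (length(times) / n_seg)))
  virial <- 0
  counts <- NULL
  rdf_counts <- NULL
  n_snapshots <- 0L
  snaps <- list()
  for (sg in seg) {
    res <- run_dmd(state, spec, max(sg) - state$time, snapshot_times = sg,
                   engine = config$engine, rdf_grid = rdf_grid,
                   keep_snapshots = keep_snapshots,
                   max_events = config$max_events)
    state <- res$state
    virial <- virial + res$virial
    counts <- if (is.null(counts)) res$counts else counts + res$counts
    if (!is.null(res$rdf_counts))
      rdf_counts <- if (is.null(rdf_counts)) res$rdf_counts
                    else rdf_counts + res$rdf_counts
    n_snapshots <- n_snapshots + res$n_snapshots
    if (keep_snapshots) snaps <- c(snaps, res$snapshots)
    pick <- which(runif(state$N) < 0.5)
    if (length(pick)) {
      v <- state$velocities
      v[pick, ] <- matrix(rnorm(3 * length(pick)), ncol = 3)
      v <- sweep(v, 2, colMeans(v))
      state$velocities <- v
    }
  }
  out <- list(state = state, virial = virial, counts = counts,
              n_snapshots = n_snapshots, snapshot_times = times)
  if (!is.null(rdf_counts)) out$rdf_counts <- rdf_counts
  if (keep_snapshots) out$snapshots <- snaps
  out
}

#' Simulate one state point and estimate its RDF
#'
#' End-to-end driver: FCC placement, Maxwell-Boltzmann velocities, two-phase
#' equilibration, NVE production with in-flight pair histogramming, and
#' normalization to g(r).
#'
#' @param spec a [make_spec()] potential.
#' @param config a [sim_config()].
#' @param grid a [radial_grid()]; defaults to the package grid clipped to
#'   L/2.
#' @param theta named parameter point attached to the sample (defaults to
#'   `phi` from the config).
#' @return an `rdf_sample`.
#' @export
simulate_rdf <- function(spec, config, grid = NULL, theta = NULL) {
  L <- box_length(config$N, config$phi, spec$sigma)
  if (is.null(grid)) {
    rmax <- min(6 * spec$sigma, L / 2)
    grid <- radial_grid(r_max = rmax, m = round(rmax / 0.01))
  }
  pos <- init_fcc(config$N, L, spec$sigma,
                  seed = sub_seed(config$seed, "placement"))
  vel <- init_velocities(config$N, kT = 1,
                         seed = sub_seed(config$seed, "velocities"))
  state <- system_state(pos, vel, L)
  eq <- run_equilibration(state, spec, config)
  prod <- run_production(eq$state, spec, config, event_rate = eq$event_rate,
                         rdf_grid = grid)
  g <- normalize_histogram(prod$rdf_counts, config$N, L,
                           prod$n_snapshots, grid)
  if (is.null(theta)) theta <- c(phi = config$phi)
  rdf_sample(grid, g, theta = theta,
             provenance = list(seed = config$seed, N = config$N,
                               phi = config$phi, kind = spec$kind))
}
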