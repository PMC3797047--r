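#' Deterministic test fixtures
#'
#' Small, fully reproducible objects used throughout the test suite and
#' handy for demos:
#' \describe{
#'   \item{two_particle}{a 2-particle head-on state whose first event is
#'     known analytically (gap 2 sigma, relative speed 1, so a hard-sphere
#'     core collision at t = 2).}
#'   \item{ideal_gas}{uniformly random points (no interactions), for
#'     histogram-normalization checks.}
#'   \item{dilute_hs}{a ready-to-run phi = 0.01 hard-sphere configuration
#'     (state + spec + config).}
#'   \item{rank1_matrix}{an exactly rank-1 `rdf_matrix` (outer product of a
#'     smooth positive radial profile and a positive parameter profile).}
#'   \item{poly_coeff_vectors}{an `svd_model`-shaped object whose
#'     coefficient vectors are exact polynomials of the degree-rule degrees,
#'     recovered exactly by the surrogate fit.}
#' }
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return the fixture object (type depends on `kind`).
#' @export
make_fixture <- function(kind = c("two_particle", "ideal_gas", "dilute_hs",
                                  "rank1_matrix", "poly_coeff_vectors"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    two_particle = {
      pos <- rbind(c(5, 5, 5), c(8, 5, 5))
      vel <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0))
      system_state(pos, vel, L = 20)
    },
    ideal_gas = {
      old <- local_seed(seed)
      on.exit(restore_seed(old))
      N <- 400L
      L <- 10
      list(positions = matrix(runif(3 * N, 0, L), ncol = 3), N = N, L = L)
    },
    dilute_hs = {
      cfg <- sim_config(phi = 0.01, N = 108L, seed = seed,
                        snapshot_count = 50L, production_events = 20)
      spec <- make_spec("hs")
      L <- box_length(cfg$N, cfg$phi)
      state <- system_state(
        init_fcc(cfg$N, L, seed = sub_seed(seed, "placement")),
        init_velocities(cfg$N, seed = sub_seed(seed, "velocities")), L)
      list(state = state, spec = spec, config = cfg)
    },
    rank1_matrix = {
      grid <- radial_grid(r_max = 6, m = 60L)
      a <- seq(0.5, 2, length.out = 8)           # parameter profile
      b <- 1 + exp(-grid$centers)                # radial profile
      rdf_matrix(grid, data.frame(phi = seq(0.1, 0.38, length.out = 8)),
                 outer(a, b))
    },
    poly_coeff_vectors = {
      k <- 16L
      phi <- seq(0.05, 0.45, length.out = k)
      p <- 3L
      u <- sapply(seq_len(p), function(n) {
        cf <- (seq_len(n + 4) - 2) / (n + 3)     # degree n+3 polynomial
        rowSums(outer(phi, seq_along(cf) - 1, "^") *
                  rep(cf, each = k))
      })
      list(params = data.frame(phi = phi), u = u, p = p,
           degrees = seq_len(p) + 3L)
    })
}
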