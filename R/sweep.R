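#' Single-phase guard for square-well state points
#'
#' Conservative rejection rule keeping sweeps outside the liquid-vapor dome
#' and the freezing transition.  A square-well system at attractive strength
#' eps and kT = 1 is equivalent to eps = 1 at temperature T = 1/eps, so a
#' point is accepted when T = 1/eps lies above the critical temperature for
#' its well width (with a safety margin), or when eps <= 0 (repulsive-free
#' hard spheres).  Critical temperatures for lambda between 1.125 and 1.75
#' are linearly interpolated from published square-well coexistence studies;
#' the freezing bound phi < 0.494 applies throughout.  The rule is
#' deliberately rectangular (independent of phi inside the dome's range) and
#' can be replaced via the `guard` argument of [sweep_spec()].
#'
#' @param phi packing fraction(s).
#' @param eps attractive strength(s) (kT units).
#' @param lambda well width(s).
#' @return logical: `TRUE` if the point is acceptably single-phase.
#' @export
phase_guard <- function(phi, eps, lambda) {
  tc_tab <- data.frame(lambda = c(1.05, 1.125, 1.25, 1.375, 1.5, 1.65, 1.75),
                       tc = c(0.48, 0.59, 0.764, 0.974, 1.219, 1.56, 1.811))
  tc <- stats::approx(tc_tab$lambda, tc_tab$tc, xout = lambda, rule = 2)$y
  ok_fluid <- phi < 0.494
  ok_phase <- eps <= 0 | (1 / pmax(eps, 1e-12)) > 1.02 * tc
  ok_fluid & ok_phase
}

#' Define a parameter sweep
#'
#' A sweep varies one or two parameters of a potential family over uniform
#' grids while the rest stay fixed, one simulation per point.
#'
#' @param potential `"hs"`, `"sw"` or `"double_sw"`.
#' @param sweep named list of `c(min, max)` ranges for the swept
#'   parameter(s); names from `phi`, `epsilon`, `lambda`.
#' @param k points per swept axis ("k equally distributed points"); a
#'   two-axis sweep runs the full k x k Cartesian grid (row-major, first
#'   axis slowest).
#' @param fixed named list of the fixed parameters (`phi`, `epsilon`,
#'   `lambda`, `boundaries`, `depths` as the potential requires).
#' @param N particles per simulation.
#' @param seed master seed; per-point seeds are a pure function of
#'   (master seed, point index).
#' @param config_args extra arguments passed to [sim_config()].
#' @param guard exclusion rule `function(phi, eps, lambda) -> logical`;
#'   points failing it are rejected at spec time.  Default [phase_guard()].
#' @return a `sweep_spec`.
#' @export
sweep_spec <- function(potential = c("hs", "sw", "double_sw"), sweep, k,
                       fixed = list(), N = 256L, seed = 1L,
                       config_args = list(), guard = phase_guard) {
  potential <- match.arg(potential)
  stopifnot(is.list(sweep), length(sweep) %in% c(1L, 2L), k >= 2)
  ok_names <- c("phi", "epsilon", "lambda")
  if (!all(names(sweep) %in% ok_names))
    stop("swept parameters must be among: ", paste(ok_names, collapse = ", "))
  for (rg in sweep)
    if (length(rg) != 2L || rg[2] <= rg[1])
      stop("each sweep range must be c(min, max) with min < max")
  structure(list(potential = potential, sweep = sweep, k = as.integer(k),
                 fixed = fixed, N = as.integer(N), seed = as.integer(seed),
                 config_args = config_args, guard = guard),
            class = "sweep_spec")
}

#' Enumerate the parameter table of a sweep
#'
#' Uniform grid over each swept range; two-parameter sweeps produce the full
#' Cartesian grid in row-major order.  Points rejected by the guard are
#' dropped (with reasons attached); an empty result is an error.
#'
#' @param spec a [sweep_spec()].
#' @return data frame of parameter points (attribute `rejected` lists
#'   excluded points).
#' @export
enumerate_points <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  axes <- lapply(spec$sweep, function(rg)
    seq(rg[1], rg[2], length.out = spec$k))
  pts <- if (length(axes) == 1L) {
    stats::setNames(data.frame(axes[[1]]), names(spec$sweep))
  } else {
    g <- expand.grid(b = axes[[2]], a = axes[[1]])  # first axis slowest
    stats::setNames(data.frame(g$a, g$b), names(spec$sweep))
  }
  getp <- function(nm, default) {
    if (!is.null(pts[[nm]])) pts[[nm]]
    else if (!is.null(spec$fixed[[nm]])) rep(spec$fixed[[nm]], nrow(pts))
    else rep(default, nrow(pts))
  }
  phi <- getp("phi", NA_real_)
  if (anyNA(phi)) stop("phi must be swept or fixed")
  eps <- getp("epsilon", if (spec$potential == "hs") 0 else NA_real_)
  lam <- getp("lambda", if (spec$potential == "hs") 1 else NA_real_)
  if (spec$potential == "double_sw") {
    # guard on the deepest shell and the outermost boundary
    eps <- rep(max(-min(spec$fixed$depths), 0), nrow(pts))
    lam <- rep(max(spec$fixed$boundaries), nrow(pts))
  }
  if (anyNA(eps) || anyNA(lam))
    stop("square-well sweeps need epsilon and lambda (swept or fixed)")
  ok <- spec$guard(phi, eps, lam)
  rejected <- pts[!ok, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- "outside single-phase guard"
  pts <- pts[ok, , drop = FALSE]
  if (nrow(pts) == 0) stop("spec error: no points survive the exclusion rule")
  rownames(pts) <- NULL
  attr(pts, "rejected") <- rejected
  pts
}

point_potential <- function(spec, point) {
  get1 <- function(nm, default = NULL) {
    if (!is.null(point[[nm]])) point[[nm]]
    else if (!is.null(spec$fixed[[nm]])) spec$fixed[[nm]]
    else default
  }
  switch(spec$potential,
         hs = make_spec("hs"),
         sw = make_spec("sw", list(lambda = get1("lambda"),
                                   epsilon = get1("epsilon"))),
         double_sw = make_spec("double_sw",
                               list(boundaries = spec$fixed$boundaries,
                                    depths = spec$fixed$depths)))
}

#' Run a full parameter sweep
#'
#' One simulation and RDF per enumerated point, with independent derived
#' seeds, assembled into an [rdf_matrix()].  When `cache_dir` is given each
#' completed point is persisted as tab-separated text and interrupted sweeps
#' resume from the cached points, yielding a matrix identical to an
#' uninterrupted run.
#'
#' @param spec a [sweep_spec()].
#' @param cache_dir optional directory for per-point caching/resumption.
#' @param progress print one line per completed point.
#' @return an `rdf_matrix` (rows ordered as [enumerate_points()]).
#' @export
run_sweep <- function(spec, cache_dir = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  pts <- enumerate_points(spec)
  # one shared grid: r_max limited by the densest box in the sweep
  phis <- if (!is.null(pts$phi)) pts$phi else rep(spec$fixed$phi, nrow(pts))
  Lmin <- box_length(spec$N, max(phis))
  rmax <- min(6, Lmin / 2)
  grid <- radial_grid(r_max = rmax, m = max(2L, round(rmax / 0.01)))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  samples <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("point_%04d.tsv", i)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      tab <- read.table(cache_file, header = TRUE, sep = "\t")
      samples[[i]] <- rdf_sample(grid, tab$g,
                                 theta = unlist(pts[i, , drop = FALSE]),
                                 provenance = list(cached = TRUE))
      next
    }
    pot <- point_potential(spec, pts[i, , drop = FALSE])
    pseed <- as.integer((sub_seed(spec$seed, "sweep") + 97561 * i) %%
                          2147483011)
    cfg <- do.call(sim_config, c(list(phi = pts$phi[i] %||% spec$fixed$phi,
                                      N = spec$N, seed = pseed),
                                 spec$config_args))
    s <- tryCatch(
      simulate_rdf(pot, cfg, grid = grid,
                   theta = unlist(pts[i, , drop = FALSE])),
      error = function(e)
        stop("sweep point ", i, " (",
             paste(names(pts), signif(unlist(pts[i, ]), 4), sep = "=",
                   collapse = ", "), ") failed: ", conditionMessage(e)))
    samples[[i]] <- s
    if (!is.null(cache_file))
      write.table(data.frame(r = sprintf("%.17g", grid$centers),
                             g = sprintf("%.17g", s$values)), cache_file,
                  sep = "\t", row.names = FALSE, quote = FALSE)
    if (progress)
      message(sprintf("point %d/%d done", i, nrow(pts)))
  }
  m <- build_rdf_matrix(samples)
  m$params <- pts
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
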