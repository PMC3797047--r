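#' Uniform radial grid for g(r)
#'
#' Bins are half-open intervals `[r_b, r_{b+1})` of equal width from 0 to
#' `r_max`; distances exactly at `r_max` are excluded.  The default
#' resolution is 0.01 sigma over (0, 6 sigma], fine enough to resolve the
#' contact discontinuity.
#'
#' @param r_max outer edge of the histogram (must satisfy `r_max <= L/2`
#'   for every contributing simulation).
#' @param m number of bins (>= 2).
#' @return a `radial_grid` with bin `edges` and `centers`.
#' @export
radial_grid <- function(r_max = 6, m = 600L) {
  m <- as.integer(m)
  stopifnot(m >= 2, r_max > 0)
  edges <- seq(0, r_max, length.out = m + 1L)
  structure(list(r_min = 0, r_max = r_max, m = m, dr = r_max / m,
                 edges = edges,
                 centers = (edges[-1] + edges[-(m + 1L)]) / 2),
            class = "radial_grid")
}

grids_equal <- function(a, b) {
  isTRUE(all.equal(c(a$r_max, a$m), c(b$r_max, b$m), tolerance = 1e-12))
}

#' Per-bin pair counts for one snapshot
#'
#' Counts unordered pairs whose minimum-image distance falls in each bin of
#' the grid.
#'
#' @param positions `N x 3` matrix.
#' @param L box edge length; must satisfy `grid$r_max <= L/2`.
#' @param grid a [radial_grid()].
#' @return integer-valued vector of length `grid$m`.
#' @export
accumulate_pairs <- function(positions, L, grid) {
  stopifnot(inherits(grid, "radial_grid"))
  if (grid$r_max > L / 2)
    stop("configuration error: r_max exceeds L/2")
  .pair_histogram(positions, L, grid$m, grid$r_max)
}

#' Normalize accumulated pair counts to g(r)
#'
#' g(b) = counts_b * V / (n_snapshots * N(N-1)/2 * V_shell(b)) with the
#' exact shell volume V_shell = (4 pi / 3)(r_{b+1}^3 - r_b^3), so that an
#' ideal gas gives g = 1 in every bin.
#'
#' @param counts vector of per-bin pair counts summed over snapshots.
#' @param N particle count.
#' @param L box edge length.
#' @param n_snapshots number of snapshots accumulated (>= 1).
#' @param grid a [radial_grid()].
#' @return numeric vector of g(r) values on the bin centers.
#' @export
normalize_histogram <- function(counts, N, L, n_snapshots, grid) {
  stopifnot(inherits(grid, "radial_grid"), length(counts) == grid$m)
  if (n_snapshots < 1) stop("need at least one snapshot")
  V <- L^3
  vshell <- (4 * pi / 3) * diff(grid$edges^3)
  npairs <- N * (N - 1) / 2
  counts * V / (n_snapshots * npairs * vshell)
}

#' One measured g(r) curve
#'
#' @param grid a [radial_grid()].
#' @param values g(r) on the bin centers (finite, non-negative).
#' @param theta named numeric parameter point (e.g. `c(phi = 0.3)`).
#' @param provenance free-form list (seed, config digest).
#' @return an `rdf_sample`.
#' @export
rdf_sample <- function(grid, values, theta, provenance = list()) {
  stopifnot(inherits(grid, "radial_grid"), length(values) == grid$m)
  if (any(!is.finite(values)) || any(values < 0))
    stop("g(r) values must be finite and non-negative")
  if (is.null(names(theta)) || any(!nzchar(names(theta))))
    stop("'theta' must be a named numeric vector")
  structure(list(grid = grid, values = as.numeric(values),
                 theta = theta, provenance = provenance),
            class = "rdf_sample")
}

#' @export
print.rdf_sample <- function(x, ...) {
  cat(sprintf("rdf_sample: m = %d bins on (0, %g], theta = {%s}\n",
              x$grid$m, x$grid$r_max,
              paste(names(x$theta), signif(x$theta, 4), sep = " = ",
                    collapse = ", ")))
  invisible(x)
}

#' Stack RDF samples into the sweep matrix G
#'
#' Rows are parameter points (in the order given), columns are radial bins.
#'
#' @param samples list of `rdf_sample`s sharing one grid, with distinct
#'   parameter points.
#' @return an `rdf_matrix` with fields `grid`, `params` (data frame, one row
#'   per sample) and `values` (k x m matrix).
#' @export
build_rdf_matrix <- function(samples) {
  stopifnot(length(samples) >= 2)
  if (!all(vapply(samples, inherits, TRUE, "rdf_sample")))
    stop("all elements must be rdf_sample objects")
  g0 <- samples[[1]]$grid
  for (s in samples)
    if (!grids_equal(s$grid, g0)) stop("assembly error: grid mismatch")
  params <- do.call(rbind, lapply(samples, function(s)
    as.data.frame(as.list(s$theta))))
  if (anyDuplicated(params)) stop("assembly error: duplicate parameter points")
  values <- do.call(rbind, lapply(samples, function(s) s$values))
  rdf_matrix(g0, params, values)
}

#' @rdname build_rdf_matrix
#' @param grid a [radial_grid()].
#' @param params data frame of k parameter points.
#' @param values k x m matrix of g(r) rows.
#' @export
rdf_matrix <- function(grid, params, values) {
  stopifnot(inherits(grid, "radial_grid"), is.matrix(values),
            nrow(values) == nrow(params), ncol(values) == grid$m)
  if (nrow(values) < 2) stop("need k >= 2 parameter points")
  if (ncol(values) <= nrow(values))
    stop("need more radial bins than parameter points (m > k)")
  structure(list(grid = grid, params = as.data.frame(params),
                 values = unname(values)),
            class = "rdf_matrix")
}

#' @export
print.rdf_matrix <- function(x, ...) {
  cat(sprintf("rdf_matrix: k = %d parameter points x m = %d bins; swept: %s\n",
              nrow(x$values), ncol(x$values),
              paste(names(x$params), collapse = ", ")))
  invisible(x)
}

#' Write / read an RDF matrix as tab-separated text
#'
#' First column holds the bin centers; one column per parameter point.  A
#' commented header block (`# key: value`) carries the grid and the
#' parameter table.
#'
#' @param x an `rdf_matrix`.
#' @param path file path.
#' @export
write_rdf_matrix <- function(x, path) {
  stopifnot(inherits(x, "rdf_matrix"))
  hdr <- c(sprintf("# rdfsvd rdf_matrix v1"),
           sprintf("# r_max: %.17g", x$grid$r_max),
           sprintf("# m: %d", x$grid$m),
           sprintf("# param_names: %s", paste(names(x$params), collapse = " ")),
           vapply(seq_len(nrow(x$params)), function(i)
             sprintf("# theta_%d: %s", i,
                     paste(sprintf("%.17g", as.numeric(x$params[i, ])),
                           collapse = " ")), ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- cbind(r = x$grid$centers, t(x$values))
  colnames(tab) <- c("r", paste0("theta", seq_len(nrow(x$values))))
  write.table(format(tab, digits = 17, trim = TRUE), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdf_matrix
#' @return `read_rdf_matrix` returns the `rdf_matrix`.
#' @export
read_rdf_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot open '", path, "'")
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  if (!any(grepl("rdfsvd rdf_matrix v1", hdr)))
    stop("load error: not an rdfsvd rdf_matrix file")
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, ": "), hdr)]
    sub(paste0("^# ", key, ": "), "", ln)
  }
  r_max <- as.numeric(getv("r_max"))
  m <- as.integer(getv("m"))
  pnames <- strsplit(getv("param_names"), " ")[[1]]
  tlines <- hdr[grepl("^# theta_", hdr)]
  params <- do.call(rbind, lapply(tlines, function(ln)
    as.numeric(strsplit(sub("^# theta_[0-9]+: ", "", ln), " ")[[1]])))
  params <- as.data.frame(params)
  names(params) <- pnames
  tab <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                    sep = "\t")
  values <- t(as.matrix(tab[, -1, drop = FALSE]))
  rdf_matrix(radial_grid(r_max = r_max, m = m), params, values)
}
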