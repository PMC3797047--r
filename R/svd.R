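#' Singular value decomposition of an RDF matrix
#'
#' Thin SVD `G = U S V'` of the k x m sweep matrix.  Columns of `V` are the
#' basis vectors (functions of r), columns of `U` the coefficient vectors
#' (functions of the swept parameters).  Singular values are sorted
#' non-increasing; the sign of each basis vector is fixed so its
#' largest-magnitude entry is positive (the coefficient vector is flipped to
#' match), making the output deterministic across LAPACK backends.
#'
#' @param matrix an [rdf_matrix()].
#' @return an `svd_model` with `d` (singular values), `u` (k x k), `v`
#'   (m x k), plus the grid and parameter table.
#' @export
decompose <- function(matrix) {
  stopifnot(inherits(matrix, "rdf_matrix"))
  G <- matrix$values
  if (any(!is.finite(G))) stop("input error: non-finite entries in G")
  s <- svd(G)
  for (n in seq_along(s$d)) {
    vmax <- which.max(abs(s$v[, n]))
    if (s$v[vmax, n] < 0) {
      s$v[, n] <- -s$v[, n]
      s$u[, n] <- -s$u[, n]
    }
  }
  structure(list(d = s$d, u = s$u, v = s$v, grid = matrix$grid,
                 params = matrix$params),
            class = "svd_model")
}

#' @export
print.svd_model <- function(x, ...) {
  cat(sprintf("svd_model: k = %d, m = %d; leading singular values: %s\n",
              nrow(x$u), nrow(x$v),
              paste(signif(utils::head(x$d, 6), 4), collapse = ", ")))
  invisible(x)
}

#' Truncation rank from a relative singular-value threshold
#'
#' Largest `p` with `sigma_p >= delta * sigma_1`.
#'
#' @param singular_values non-increasing, non-negative.
#' @param delta relative threshold (default 1e-6).
#' @return integer rank p >= 1.
#' @export
truncation_rank <- function(singular_values, delta = 1e-6) {
  sv <- as.numeric(singular_values)
  if (length(sv) == 0 || sv[1] <= 0)
    stop("degenerate input: all singular values are zero")
  if (is.unsorted(rev(sv))) stop("singular values must be non-increasing")
  max(which(sv >= delta * sv[1]))
}

#' Rank-p reconstruction of the sweep matrix
#'
#' Sum of the first `p` singular triplets; by the Eckart-Young theorem this
#' is the best rank-p approximation of G in Frobenius norm.
#'
#' @param model an [decompose()] result.
#' @param p rank, `1 <= p <= k`.
#' @return k x m matrix.
#' @export
reconstruct_truncated <- function(model, p) {
  stopifnot(inherits(model, "svd_model"))
  k <- length(model$d)
  if (p < 1 || p > k) stop("rank p out of range")
  idx <- seq_len(p)
  model$u[, idx, drop = FALSE] %*%
    (model$d[idx] * t(model$v[, idx, drop = FALSE]))
}

# ---- polynomial machinery --------------------------------------------------
# Fits are performed in Chebyshev basis on the parameter mapped to [-1, 1]
# (conditioning at degree ~9 on small grids); coefficients can be exported
# to the monomial basis of the original variable for inspection.

scale_to_unit <- function(x, lo, hi) {
  if (hi <= lo) stop("degenerate parameter domain")
  2 * (x - lo) / (hi - lo) - 1
}

cheb_design <- function(x, degree) {
  n <- length(x)
  Tm <- matrix(0, n, degree + 1L)
  Tm[, 1] <- 1
  if (degree >= 1) Tm[, 2] <- x
  if (degree >= 2)
    for (j in 3:(degree + 1L)) Tm[, j] <- 2 * x * Tm[, j - 1] - Tm[, j - 2]
  Tm
}

cheb_eval <- function(coef, x) {
  # Clenshaw recurrence
  d <- length(coef) - 1L
  b1 <- 0; b2 <- 0
  if (d >= 1)
    for (j in seq(d + 1L, 2L)) {
      b0 <- 2 * x * b1 - b2 + coef[j]
      b2 <- b1; b1 <- b0
    }
  x * b1 - b2 + coef[1]
}

# Chebyshev -> monomial coefficients (in the scaled variable)
cheb_to_monomial <- function(coef) {
  d <- length(coef) - 1L
  polys <- vector("list", d + 1L)
  polys[[1]] <- 1
  if (d >= 1) polys[[2]] <- c(0, 1)
  if (d >= 2)
    for (j in 3:(d + 1L))
      polys[[j]] <- c(0, 2 * polys[[j - 1]]) -
        c(polys[[j - 2]], numeric(j - length(polys[[j - 2]])))
  out <- numeric(d + 1L)
  for (j in seq_len(d + 1L)) {
    pj <- polys[[j]]
    out[seq_along(pj)] <- out[seq_along(pj)] + coef[j] * pj
  }
  out
}

# shift monomial coefficients from x = 2(theta-lo)/(hi-lo) - 1 to theta
monomial_rescale <- function(coef, lo, hi) {
  # substitute x = a*theta + b
  a <- 2 / (hi - lo)
  b <- -1 - 2 * lo / (hi - lo)
  d <- length(coef) - 1L
  out <- numeric(d + 1L)
  # accumulate coef[j+1] * (a t + b)^j expanded binomially
  for (j in 0:d) {
    bin <- choose(j, 0:j) * a^(0:j) * b^(j - (0:j))
    out[1:(j + 1L)] <- out[1:(j + 1L)] + coef[j + 1L] * bin
  }
  out
}

#' Fit low-order polynomial surrogates to the coefficient vectors
#'
#' Each retained coefficient vector u_n (a function of the swept parameter,
#' or of two parameters) is replaced by a least-squares polynomial whose
#' degree grows linearly with the rank index (`degree_rule`, default
#' `n + 3`).  One-parameter sweeps use a univariate polynomial; two-parameter
#' sweeps a bivariate polynomial with the same rule applied to the total
#' degree.
#'
#' @param model an [decompose()] result.
#' @param p number of ranks to fit.
#' @param degree_rule function mapping rank index n to polynomial degree.
#' @return a `poly_surrogate`: per-rank fits, domains, and log10 RMS
#'   residuals.
#' @export
fit_coefficient_polynomials <- function(model, p,
                                        degree_rule = function(n) n + 3) {
  stopifnot(inherits(model, "svd_model"))
  params <- model$params
  nv <- ncol(params)
  if (!nv %in% c(1L, 2L))
    stop("surrogates support one- or two-parameter sweeps")
  k <- nrow(params)
  domain <- lapply(params, range)
  xs <- lapply(seq_len(nv), function(j)
    scale_to_unit(params[[j]], domain[[j]][1], domain[[j]][2]))
  fits <- vector("list", p)
  for (n in seq_len(p)) {
    d <- as.integer(degree_rule(n))
    if (nv == 1L) {
      if (d >= k) stop("ill-posed fit: degree ", d, " >= k = ", k)
      X <- cheb_design(xs[[1]], d)
    } else {
      expo <- expand.grid(i = 0:d, j = 0:d)
      expo <- expo[expo$i + expo$j <= d, , drop = FALSE]
      if (nrow(expo) >= k)
        stop("ill-posed fit: ", nrow(expo), " coefficients >= k = ", k)
      Tx <- cheb_design(xs[[1]], d)
      Ty <- cheb_design(xs[[2]], d)
      X <- Tx[, expo$i + 1L, drop = FALSE] * Ty[, expo$j + 1L, drop = FALSE]
    }
    y <- model$u[, n]
    cf <- qr.solve(qr(X), y)
    resid <- y - X %*% cf
    fits[[n]] <- list(degree = d, coef = as.numeric(cf),
                      exponents = if (nv == 2L) expo else NULL,
                      rms = sqrt(mean(resid^2)))
  }
  structure(list(fits = fits, domain = domain, n_params = nv,
                 param_names = names(params), p = p),
            class = "poly_surrogate")
}

# evaluate surrogate polynomial for rank n at a named theta
surrogate_eval <- function(surr, n, theta) {
  fit <- surr$fits[[n]]
  xs <- vapply(seq_len(surr$n_params), function(j) {
    dom <- surr$domain[[j]]
    scale_to_unit(theta[[surr$param_names[j]]], dom[1], dom[2])
  }, 0)
  if (surr$n_params == 1L) {
    cheb_eval(fit$coef, xs[1])
  } else {
    Tx <- cheb_design(xs[1], fit$degree)
    Ty <- cheb_design(xs[2], fit$degree)
    sum(fit$coef * Tx[1, fit$exponents$i + 1L] * Ty[1, fit$exponents$j + 1L])
  }
}

#' Per-rank polynomial fit residuals
#'
#' The residual between each coefficient vector and its polynomial on the
#' training grid, reported as log10 of the root-mean-square.
#'
#' @param model an [decompose()] result (used for context only).
#' @param surrogate a [fit_coefficient_polynomials()] result.
#' @return numeric vector of log10 RMS residuals, one per fitted rank.
#' @export
fit_residual_report <- function(model, surrogate) {
  stopifnot(inherits(surrogate, "poly_surrogate"))
  log10(vapply(surrogate$fits, function(f) max(f$rms, 1e-300), 0))
}

#' Monomial-basis coefficients of a fitted surrogate
#'
#' Converts the internally stored Chebyshev fit for rank `n` to monomial
#' coefficients in the original (unscaled) parameter, constant term first.
#' Only available for univariate surrogates.
#'
#' @param surrogate a [fit_coefficient_polynomials()] result.
#' @param n rank index.
#' @return numeric coefficient vector `c0, c1, ...`.
#' @export
surrogate_monomials <- function(surrogate, n) {
  stopifnot(inherits(surrogate, "poly_surrogate"))
  if (surrogate$n_params != 1L)
    stop("monomial export implemented for univariate surrogates")
  dom <- surrogate$domain[[1]]
  monomial_rescale(cheb_to_monomial(surrogate$fits[[n]]$coef),
                   dom[1], dom[2])
}

#' Compact representation of a g(r) family
#'
#' Bundles the truncated SVD (singular values + basis vectors) with the
#' polynomial surrogates for the coefficient vectors: everything needed to
#' reconstruct g(r; theta) anywhere inside the swept parameter domain.
#'
#' @param model an [decompose()] result.
#' @param p truncation rank (default from [truncation_rank()] at `delta`).
#' @param delta relative singular-value threshold.
#' @param degree_rule see [fit_coefficient_polynomials()].
#' @return a `compact_representation`.
#' @export
compact_representation <- function(model, p = NULL, delta = 1e-6,
                                   degree_rule = function(n) n + 3) {
  stopifnot(inherits(model, "svd_model"))
  if (is.null(p)) p <- min(truncation_rank(model$d, delta), length(model$d))
  surr <- fit_coefficient_polynomials(model, p, degree_rule)
  structure(list(grid = model$grid, p = p, delta = delta,
                 singular_values = model$d[seq_len(p)],
                 basis = model$v[, seq_len(p), drop = FALSE],
                 surrogate = surr,
                 domain = surr$domain, param_names = surr$param_names,
                 version = "rdfsvd-compact-1"),
            class = "compact_representation")
}

#' @export
print.compact_representation <- function(x, ...) {
  cat(sprintf(
    "compact_representation: p = %d vectors, m = %d bins, params: %s\n",
    x$p, nrow(x$basis),
    paste(sprintf("%s in [%g, %g]", x$param_names,
                  vapply(x$domain, `[`, 0, 1),
                  vapply(x$domain, `[`, 0, 2)), collapse = ", ")))
  invisible(x)
}

#' Reconstruct g(r) at an interpolated parameter point
#'
#' Evaluates `g(r; theta) = sum_n sigma_n P_n(theta) v_n(r)` on the stored
#' grid.  Truncated reconstructions may dip slightly negative near sharp
#' features (a Gibbs-type artifact); values are returned unclipped.
#'
#' @param compact a [compact_representation()].
#' @param theta named parameter point, inside the stored domain.
#' @param strict if `TRUE` (default) evaluation outside the domain is an
#'   error; otherwise a warning (extrapolation is unreliable).
#' @return an `rdf_sample` (unvalidated values).
#' @export
evaluate_model <- function(compact, theta, strict = TRUE) {
  stopifnot(inherits(compact, "compact_representation"))
  theta <- unlist(theta)
  missing <- setdiff(compact$param_names, names(theta))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  for (j in seq_along(compact$param_names)) {
    nm <- compact$param_names[j]
    dom <- compact$domain[[j]]
    tol <- 1e-12 * max(1, abs(dom))
    if (theta[[nm]] < dom[1] - tol || theta[[nm]] > dom[2] + tol) {
      msg <- sprintf("theta[%s] = %g outside interpolated domain [%g, %g]",
                     nm, theta[[nm]], dom[1], dom[2])
      if (strict) stop(msg) else warning(msg)
    }
  }
  w <- vapply(seq_len(compact$p), function(n)
    compact$singular_values[n] * surrogate_eval(compact$surrogate, n, theta),
    0)
  vals <- as.numeric(compact$basis %*% w)
  structure(list(grid = compact$grid, values = vals,
                 theta = theta[compact$param_names],
                 provenance = list(reconstructed = TRUE, p = compact$p)),
            class = "rdf_sample")
}
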