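#' Static structure factor from g(r)
#'
#' S(q) = 1 + 4 pi rho int_0^{rmax} (g(r) - 1) r sin(qr)/q dr, evaluated by
#' trapezoidal quadrature on the sample's radial grid; the q -> 0 integrand
#' uses the sinc limit r^2.  The integrand uses (g - 1), which decays, so no
#' windowing is applied by default; a cosine taper over the outer 10% of the
#' range is available for short-ranged grids.
#'
#' @param sample an `rdf_sample` extending far enough that g(r_max) is close
#'   to 1.
#' @param rho number density.
#' @param q_grid wavenumbers (>= 0); default 200 points on (0, 20].
#' @param taper truncation window: `FALSE` (none, default), `"cosine"`
#'   (half-cosine roll-off over the outer 10% of the range) or `"lorch"`
#'   (Lorch window `sin(pi r/rmax)/(pi r/rmax)`, the standard choice when
#'   the radial window is short and g(r) still oscillates at `r_max`).
#' @return a `structure_factor` with fields `q`, `values`, `rho`.
#' @export
structure_factor <- function(sample, rho, q_grid = NULL, taper = FALSE) {
  stopifnot(inherits(sample, "rdf_sample"), rho > 0)
  if (is.null(q_grid)) q_grid <- seq(0.1, 20, length.out = 200)
  if (any(q_grid < 0)) stop("q must be non-negative")
  r <- sample$grid$centers
  h <- sample$values - 1
  if (isTRUE(taper)) taper <- "cosine"
  if (identical(taper, "cosine")) {
    w <- rep(1, length(r))
    r0 <- 0.9 * sample$grid$r_max
    sel <- r > r0
    w[sel] <- 0.5 * (1 + cos(pi * (r[sel] - r0) / (sample$grid$r_max - r0)))
    h <- h * w
  } else if (identical(taper, "lorch")) {
    x <- pi * r / sample$grid$r_max
    h <- h * sin(x) / x
  }
  dr <- sample$grid$dr
  vals <- vapply(q_grid, function(q) {
    f <- if (q == 0) h * r^2 else h * r * sin(q * r) / q
    # trapezoid on bin centers
    1 + 4 * pi * rho * (sum(f) - (f[1] + f[length(f)]) / 2) * dr
  }, 0)
  structure(list(q = q_grid, values = vals, rho = rho),
            class = "structure_factor")
}

#' Positivity check for a structure factor
#'
#' A physical S(q) is non-negative; a small tolerance absorbs quadrature
#' ripple from the finite integration range.
#'
#' @param sf a [structure_factor()].
#' @param tol tolerance (default 1e-3).
#' @return list with `pass`, `min` value and the `q` at the minimum.
#' @export
check_positivity <- function(sf, tol = 1e-3) {
  stopifnot(inherits(sf, "structure_factor"))
  i <- which.min(sf$values)
  list(pass = sf$values[i] >= -tol, min = sf$values[i], q_min = sf$q[i])
}

#' Average reconstruction error over a sweep
#'
#' For each parameter point, the L1 difference between measured and
#' reconstructed g(r), integrated over [sigma, 6 sigma] by the trapezoid
#' rule and normalized; the per-point errors are averaged over the sweep:
#' E = mean_theta( int |g - g~| dr / int g dr ).  The alternative
#' normalization by the window length (5 sigma) is available via
#' `normalization = "window"`.
#'
#' @param measured an [rdf_matrix()].
#' @param reconstructed k x m matrix on the same grid.
#' @param sigma core diameter (integration window is [sigma, 6 sigma],
#'   clipped to the grid).
#' @param normalization `"gr"` (divide by the integral of g) or `"window"`
#'   (divide by the window length).
#' @return scalar average error.
#' @export
average_reconstruction_error <- function(measured, reconstructed, sigma = 1,
                                         normalization = c("gr", "window")) {
  stopifnot(inherits(measured, "rdf_matrix"))
  normalization <- match.arg(normalization)
  G <- measured$values
  if (!all(dim(G) == dim(reconstructed)))
    stop("input error: shape mismatch")
  r <- measured$grid$centers
  sel <- r >= sigma & r <= 6 * sigma
  if (sum(sel) < 2) stop("grid does not cover the [sigma, 6 sigma] window")
  trapz <- function(y, x) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  rs <- r[sel]
  errs <- vapply(seq_len(nrow(G)), function(i) {
    num <- trapz(abs(G[i, sel] - reconstructed[i, sel]), rs)
    den <- if (normalization == "gr") trapz(G[i, sel], rs)
           else diff(range(rs))
    num / den
  }, 0)
  mean(errs)
}

#' Dilute-limit check of a measured RDF
#'
#' At low density g(r) -> exp(-u(r)/kT); this computes the largest absolute
#' deviation from that limit over r >= sigma (excluding bins that straddle a
#' potential discontinuity, where the histogram mixes both sides).
#'
#' @param sample an `rdf_sample` simulated at `phi <= 0.02`.
#' @param spec the [make_spec()] potential used.
#' @param phi the packing fraction of the simulation.
#' @param pad number of bin widths around each discontinuity to exclude.
#' @return list with `max_deviation`, the comparison curve and the mask
#'   used.
#' @export
low_density_check <- function(sample, spec, phi, pad = 2) {
  stopifnot(inherits(sample, "rdf_sample"))
  if (phi > 0.02)
    stop("inapplicable check: the dilute limit needs phi <= 0.02")
  r <- sample$grid$centers
  dr <- sample$grid$dr
  target <- exp(-evaluate_potential(spec, pmax(r, 1e-12)))
  disc <- spec$sigma * c(1, spec$boundaries)
  keep <- r >= spec$sigma * (1 + pad * dr / spec$sigma)
  for (d in disc) keep <- keep & abs(r - d) > pad * dr
  dev <- abs(sample$values - target)
  list(max_deviation = max(dev[keep]), target = target, mask = keep)
}

#' Carnahan-Starling compressibility factor for hard spheres
#'
#' Z = (1 + phi + phi^2 - phi^3) / (1 - phi)^3.
#'
#' @param phi packing fraction.
#' @return Z = P / (rho kT).
#' @export
carnahan_starling_z <- function(phi) {
  (1 + phi + phi^2 - phi^3) / (1 - phi)^3
}

#' Percus-Yevick hard-sphere contact value (Wertheim)
#'
#' g(sigma+) = (1 + phi/2) / (1 - phi)^2 from the analytic PY solution.
#'
#' @param phi packing fraction.
#' @return contact value of g.
#' @export
py_hs_contact <- function(phi) (1 + phi / 2) / (1 - phi)^2

#' Wertheim's analytic PY direct correlation function for hard spheres
#'
#' Inside the core (r < sigma):
#' c(r) = -lambda1 - 6 phi lambda2 (r/sigma) - (phi lambda1 / 2)(r/sigma)^3
#' with lambda1 = (1+2phi)^2/(1-phi)^4 and lambda2 = -(1+phi/2)^2/(1-phi)^4;
#' c(r) = 0 outside.
#'
#' @param r separations.
#' @param phi packing fraction.
#' @param sigma core diameter.
#' @return c(r) values.
#' @export
wertheim_py_c <- function(r, phi, sigma = 1) {
  l1 <- (1 + 2 * phi)^2 / (1 - phi)^4
  l2 <- -(1 + phi / 2)^2 / (1 - phi)^4
  x <- r / sigma
  out <- -l1 - 6 * phi * l2 * x - phi * l1 * x^3 / 2
  out[x >= 1] <- 0
  out
}
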