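# Structure factor, positivity, reconstruction error metric, dilute limit

test_that("a flat g gives S(q) = 1 and passes positivity", {
  grid <- radial_grid(r_max = 6, m = 120L)
  s <- rdf_sample(grid, rep(1, 120), c(phi = 0.2))
  sf <- structure_factor(s, rho = 0.4)
  expect_equal(sf$values, rep(1, length(sf$q)), tolerance = 1e-12)
  pos <- check_positivity(sf)
  expect_true(pos$pass)
  expect_equal(pos$min, 1, tolerance = 1e-12)
  expect_error(structure_factor(s, 0.4, q_grid = c(-1, 1)), "non-negative")
})

test_that("S(q) tends to 1 at large q and fails on corrupted g", {
  grid <- radial_grid(r_max = 6, m = 300L)
  g <- 1 + 0.5 * exp(-(grid$centers - 1.5)^2)
  s <- rdf_sample(grid, g, c(phi = 0.2))
  sf <- structure_factor(s, rho = 0.3, q_grid = seq(40, 60, length.out = 20))
  expect_lt(max(abs(sf$values - 1)), 0.01)
  bad <- s
  bad$values <- pmax(g - 2 * exp(-(grid$centers - 2)^2), 0)  # deep dip
  sfb <- structure_factor(bad, rho = 0.3)
  expect_false(check_positivity(sfb)$pass)
})

test_that("the PY structure factor matches the analytic compressibility route", {
  # oracle: S(q) = 1 / (1 - rho c_hat(q)) with Wertheim's closed-form c(r),
  # transformed by direct quadrature, independent of the package's solver
  phi <- 0.3; rho <- 6 * phi / pi
  sol <- solve_oz(make_spec("hs"), rho, "py")
  grid <- radial_grid(r_max = 10, m = 1000L)
  g <- stats::approx(sol$r, sol$g, xout = grid$centers, rule = 2)$y
  g[grid$centers < 1] <- 0
  s <- rdf_sample(grid, g, c(phi = phi))
  q <- seq(0.5, 15, length.out = 40)
  sf <- structure_factor(s, rho, q_grid = q)
  chat <- vapply(q, function(qq) {
    integrate(function(r) 4 * pi * r * wertheim_py_c(r, phi) * sin(qq * r) / qq,
              0, 1, rel.tol = 1e-10)$value
  }, 0)
  s_oracle <- 1 / (1 - rho * chat)
  expect_lt(max(abs(sf$values - s_oracle) / s_oracle), 0.01)
})

test_that("the average reconstruction error matches hand-computed quadrature", {
  fx <- make_fixture("rank1_matrix")
  expect_identical(average_reconstruction_error(fx, fx$values), 0)
  # perturb one interior bin of one row by delta
  delta <- 0.25
  bin <- 30L
  rec <- fx$values
  rec[2, bin] <- rec[2, bin] + delta
  r <- fx$grid$centers
  sel <- r >= 1 & r <= 6
  rs <- r[sel]
  trapz <- function(y, x) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  dev <- abs(rec[2, sel] - fx$values[2, sel])
  expected <- trapz(dev, rs) / trapz(fx$values[2, sel], rs) / nrow(fx$values)
  got <- average_reconstruction_error(fx, rec)
  expect_equal(got, expected, tolerance = 1e-12)
  # window normalization divides by 5 sigma instead
  gotw <- average_reconstruction_error(fx, rec, normalization = "window")
  expectedw <- trapz(dev, rs) / diff(range(rs)) / nrow(fx$values)
  expect_equal(gotw, expectedw, tolerance = 1e-12)
  expect_error(average_reconstruction_error(fx, rec[, -1]), "shape")
})

test_that("the dilute-limit check excludes discontinuity bins and rejects dense states", {
  spec <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
  grid <- radial_grid(r_max = 4, m = 80L)
  r <- grid$centers
  g <- exp(-evaluate_potential(spec, pmax(r, 0.01)))
  g[!is.finite(g)] <- 0
  # corrupt exactly the bins at the discontinuities: must not affect the stat
  g_bad <- g
  g_bad[abs(r - 1.25) < 0.05] <- 9
  s <- rdf_sample(grid, g_bad, c(phi = 0.01))
  chk <- low_density_check(s, spec, phi = 0.01)
  expect_lt(chk$max_deviation, 1e-12)
  expect_error(low_density_check(s, spec, phi = 0.1), "inapplicable")
})
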