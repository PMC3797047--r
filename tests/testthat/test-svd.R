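# SVD layer: decomposition, truncation, surrogates, compact evaluation

random_rdf_matrix <- function(k = 8L, m = 40L, seed = 1) {
  set.seed(seed)
  grid <- radial_grid(r_max = 4, m = m)
  rdf_matrix(grid, data.frame(phi = seq(0.1, 0.4, length.out = k)),
             matrix(abs(rnorm(k * m)) + 0.1, k, m))
}

test_that("the decomposition is exact, orthonormal and sign-deterministic", {
  m <- random_rdf_matrix()
  mod <- decompose(m)
  k <- nrow(m$values)
  expect_lt(max(abs(crossprod(mod$u) - diag(k))), 1e-10)
  expect_lt(max(abs(crossprod(mod$v) - diag(k))), 1e-10)
  G <- mod$u %*% (mod$d * t(mod$v))
  expect_lt(norm(G - m$values, "F") / norm(m$values, "F"), 1e-10)
  # sign convention: largest-magnitude entry of each basis vector positive
  for (n in seq_len(k))
    expect_gt(mod$v[which.max(abs(mod$v[, n])), n], 0)
  bad <- m; bad$values[1, 1] <- NaN
  expect_error(decompose(bad), "non-finite")
})

test_that("a rank-1 matrix yields sigma1 = |a||b| and a vanishing tail", {
  fx <- make_fixture("rank1_matrix")
  mod <- decompose(fx)
  a <- seq(0.5, 2, length.out = 8)
  b <- 1 + exp(-fx$grid$centers)
  expect_equal(mod$d[1], sqrt(sum(a^2)) * sqrt(sum(b^2)), tolerance = 1e-12)
  expect_lt(max(mod$d[-1]), 1e-12 * mod$d[1])
  expect_lt(norm(reconstruct_truncated(mod, 1) - fx$values, "F"), 1e-10)
})

test_that("truncation rank follows the relative threshold", {
  expect_identical(truncation_rank(c(10, 1, 1e-9), 1e-6), 2L)
  expect_identical(truncation_rank(c(5, 0, 0), 1e-6), 1L)
  expect_identical(truncation_rank(c(5, 4.999), 1e-6), 2L)
  expect_error(truncation_rank(c(0, 0)), "degenerate")
  expect_error(truncation_rank(c(1, 2, 3)), "non-increasing")
})

test_that("truncated reconstruction satisfies the Eckart-Young identity", {
  m <- random_rdf_matrix(k = 8L, m = 40L, seed = 7)
  mod <- decompose(m)
  errs <- vapply(1:8, function(p)
    norm(reconstruct_truncated(mod, p) - m$values, "F"), 0)
  # the truncation error equals the singular tail exactly
  tails <- vapply(1:8, function(p) sqrt(sum(mod$d[-seq_len(p)]^2)), 0)
  expect_equal(errs, tails, tolerance = 1e-10)
  expect_true(all(diff(errs) <= 1e-12))
  # independent best-rank-p oracle from the eigendecomposition of G'G
  ev <- eigen(crossprod(t(m$values)), symmetric = TRUE)$values
  tails_eig <- vapply(1:8, function(p)
    sqrt(sum(pmax(ev[-seq_len(p)], 0))), 0)
  expect_equal(errs, tails_eig, tolerance = 1e-8)
  expect_error(reconstruct_truncated(mod, 0), "range")
  expect_error(reconstruct_truncated(mod, 9), "range")
})

test_that("exact polynomial coefficient vectors are recovered to machine precision", {
  fx <- make_fixture("poly_coeff_vectors")
  mod <- structure(list(d = rep(1, fx$p), u = fx$u,
                        v = matrix(0, 50, fx$p), params = fx$params,
                        grid = radial_grid(6, 50L)),
                   class = "svd_model")
  surr <- fit_coefficient_polynomials(mod, p = fx$p)
  resid <- fit_residual_report(mod, surr)
  expect_true(all(resid <= -12))
  # monomial export reproduces the generating coefficients
  for (n in seq_len(fx$p)) {
    cf <- (seq_len(n + 4) - 2) / (n + 3)
    got <- surrogate_monomials(surr, n)
    expect_equal(got, cf, tolerance = 1e-6)
  }
})

test_that("bivariate surrogates fit separable polynomials exactly", {
  g <- expand.grid(eps = seq(0.2, 1, length.out = 5),
                   phi = seq(0.1, 0.4, length.out = 5))
  params <- data.frame(phi = g$phi, eps = g$eps)
  u <- cbind(params$phi * params$eps)
  mod <- structure(list(d = 1, u = u, v = matrix(0, 60, 1), params = params,
                        grid = radial_grid(6, 60L)),
                   class = "svd_model")
  surr <- fit_coefficient_polynomials(mod, p = 1,
                                      degree_rule = function(n) 2)
  expect_lt(surr$fits[[1]]$rms, 1e-13)
  val <- rdfsvd:::surrogate_eval(surr, 1, list(phi = 0.2345, eps = 0.678))
  expect_equal(val, 0.2345 * 0.678, tolerance = 1e-10)
  expect_error(fit_coefficient_polynomials(mod, 1,
                                           degree_rule = function(n) 6),
               "ill-posed")
})

test_that("white-noise coefficient vectors leave the expected fit residual", {
  set.seed(31)
  k <- 64L
  sigma_noise <- 0.01
  u <- matrix(rnorm(k, sd = sigma_noise), k, 1)
  mod <- structure(list(d = 1, u = u, v = matrix(0, 80, 1),
                        params = data.frame(phi = seq(0.1, 0.4,
                                                      length.out = k)),
                        grid = radial_grid(6, 80L)),
                   class = "svd_model")
  surr <- fit_coefficient_polynomials(mod, p = 1)
  d <- surr$fits[[1]]$degree
  expected <- sigma_noise * sqrt(1 - (d + 1) / k)
  expect_equal(surr$fits[[1]]$rms, expected, tolerance = 0.35)
})

test_that("the compact model reproduces a smooth analytic family at interpolated points", {
  # g(r; phi) = 1 + phi exp(-r): exactly rank 2, linear coefficients
  grid <- radial_grid(r_max = 5, m = 80L)
  phis <- seq(0.1, 0.4, length.out = 10)
  G <- t(sapply(phis, function(p) 1 + p * exp(-grid$centers)))
  m <- rdf_matrix(grid, data.frame(phi = phis), G)
  compact <- compact_representation(decompose(m), p = 2)
  for (phi in c(0.125, 0.2781, 0.4)) {
    s <- evaluate_model(compact, c(phi = phi))
    expect_lt(max(abs(s$values - (1 + phi * exp(-grid$centers)))), 1e-6)
  }
  # training point matches the truncated reconstruction row
  row3 <- reconstruct_truncated(decompose(m), 2)[3, ]
  s3 <- evaluate_model(compact, c(phi = phis[3]))
  expect_lt(max(abs(s3$values - row3)), 1e-8)
  expect_error(evaluate_model(compact, c(phi = 0.45)), "domain")
  expect_warning(evaluate_model(compact, c(phi = 0.45), strict = FALSE),
                 "domain")
  expect_error(evaluate_model(compact, c(eps = 0.2)), "missing")
})
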