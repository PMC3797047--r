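# Histogram estimator, normalization, and sweep-matrix assembly

test_that("pair accumulation counts minimum-image pairs into the right bins", {
  grid <- radial_grid(r_max = 3, m = 30L)
  pos <- rbind(c(1, 1, 1), c(2.5, 1, 1))   # separation 1.5
  counts <- accumulate_pairs(pos, L = 10, grid)
  expect_identical(sum(counts), 1)
  expect_identical(which(counts == 1), 16L)  # bin [1.5, 1.6)
  # periodic wrap: separation through the boundary
  pos2 <- rbind(c(0.2, 5, 5), c(9.35, 5, 5))  # image distance 0.85
  counts2 <- accumulate_pairs(pos2, L = 10, grid)
  expect_identical(which(counts2 == 1), 9L)
  expect_error(accumulate_pairs(pos, L = 4, grid), "r_max")
})

test_that("counts are bounded by the number of pairs and match shell volumes", {
  fx <- make_fixture("ideal_gas", seed = 2)
  grid <- radial_grid(r_max = 5, m = 25L)
  counts <- accumulate_pairs(fx$positions, fx$L, grid)
  expect_lte(sum(counts), fx$N * (fx$N - 1) / 2)
  # Poisson check against the ideal-gas shell-volume expectation
  vshell <- (4 * pi / 3) * diff(grid$edges^3)
  expected <- fx$N * (fx$N - 1) / 2 * vshell / fx$L^3
  z <- (counts - expected) / sqrt(expected)
  expect_lt(max(abs(z[expected > 5])), 5)
})

test_that("normalization gives g = 1 for ideal gas and 0 in empty bins", {
  grid <- radial_grid(r_max = 5, m = 25L)
  total <- 0
  nsnap <- 40L
  for (s in seq_len(nsnap)) {
    fx <- make_fixture("ideal_gas", seed = 100 + s)
    total <- total + accumulate_pairs(fx$positions, fx$L, grid)
  }
  fx <- make_fixture("ideal_gas", seed = 101)
  g <- normalize_histogram(total, fx$N, fx$L, nsnap, grid)
  expect_lt(max(abs(g - 1)), 0.05)
  expect_identical(normalize_histogram(numeric(25), 10, 10, 5, grid),
                   numeric(25))
  expect_error(normalize_histogram(total, fx$N, fx$L, 0, grid), "snapshot")
})

test_that("a dilute hard-sphere run reproduces the step-function limit", {
  fx <- make_fixture("dilute_hs")
  eq <- run_equilibration(fx$state, fx$spec, fx$config)
  grid <- radial_grid(r_max = 5, m = 100L)
  prod <- run_production(eq$state, fx$spec, fx$config,
                         event_rate = eq$event_rate, rdf_grid = grid)
  g <- normalize_histogram(prod$rdf_counts, fx$config$N, fx$state$L,
                           prod$n_snapshots, grid)
  r <- grid$centers
  expect_identical(max(g[r < 0.95]), 0)
  expect_lt(abs(mean(g[r > 1.1 & r < 4]) - 1), 0.05)
})

test_that("doubling the snapshot count shrinks the standard error by sqrt(2)", {
  grid <- radial_grid(r_max = 4, m = 8L)
  est <- function(nsnap, rep) {
    total <- 0
    for (s in seq_len(nsnap))
      total <- total + accumulate_pairs(
        make_fixture("ideal_gas", seed = 1000 * rep + s)$positions, 10, grid)
    normalize_histogram(total, 400, 10, nsnap, grid)
  }
  g1 <- sapply(1:12, function(r) est(2L, r))
  g2 <- sapply(1:12, function(r) est(8L, r))   # 4x snapshots -> half the SE
  ratio <- apply(g1, 1, sd) / apply(g2, 1, sd)
  expect_gt(median(ratio), 1.35)
  expect_lt(median(ratio), 3.2)
})

test_that("matrix assembly demands one grid and distinct ordered parameters", {
  grid <- radial_grid(r_max = 6, m = 60L)
  mk <- function(phi, g = grid) rdf_sample(g, rep(1, g$m), c(phi = phi))
  m <- build_rdf_matrix(list(mk(0.1), mk(0.2), mk(0.3)))
  expect_identical(dim(m$values), c(3L, 60L))
  expect_identical(m$params$phi, c(0.1, 0.2, 0.3))
  expect_error(build_rdf_matrix(list(mk(0.1),
                                     mk(0.2, radial_grid(6, 50L)))),
               "grid mismatch")
  expect_error(build_rdf_matrix(list(mk(0.1), mk(0.1))), "duplicate")
  expect_error(rdf_matrix(grid, data.frame(phi = 1:60),
                          matrix(1, 60, 60)), "m > k")
})

test_that("RDF matrices round-trip through the TSV form", {
  fx <- make_fixture("rank1_matrix")
  path <- tempfile(fileext = ".tsv")
  write_rdf_matrix(fx, path)
  back <- read_rdf_matrix(path)
  expect_equal(back$values, fx$values, tolerance = 0)
  expect_equal(back$params$phi, fx$params$phi, tolerance = 0)
  expect_identical(back$grid$m, fx$grid$m)
  expect_error(read_rdf_matrix(tempfile()), "cannot open|No such")
  junk <- tempfile(); writeLines("not a matrix", junk)
  expect_error(read_rdf_matrix(junk), "load error")
})
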