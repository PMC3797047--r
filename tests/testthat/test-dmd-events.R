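# Exact pair-event prediction and resolution mechanics

test_that("head-on kinematics give the textbook core collision", {
  hs <- make_spec("hs")
  ev <- predict_pair_event(c(0, 0, 0), c(0.5, 0, 0),
                           c(3, 0, 0), c(-0.5, 0, 0), hs)
  expect_identical(ev$type, "core_collision")
  expect_equal(ev$time, 2, tolerance = 1e-14)  # gap 2 sigma, speed 1
  # receding: no event
  ev2 <- predict_pair_event(c(0, 0, 0), c(-0.5, 0, 0),
                            c(3, 0, 0), c(0.5, 0, 0), hs)
  expect_identical(ev2$type, "none")
})

test_that("an impact parameter above sigma misses the core", {
  hs <- make_spec("hs")
  # particle 2 passes by with closest approach 1.2 sigma
  ev <- predict_pair_event(c(0, 0, 0), c(0, 0, 0),
                           c(-4, 1.2, 0), c(1, 0, 0), hs)
  expect_identical(ev$type, "none")
  # independent fine-step trajectory scan confirms no approach below sigma
  t <- seq(0, 10, by = 1e-3)
  d <- sqrt((-4 + t)^2 + 1.2^2)
  expect_gte(min(d), 1.2)
})

test_that("approach into a square well predicts the shell crossing", {
  sw <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
  ev <- predict_pair_event(c(0, 0, 0), c(0.5, 0, 0),
                           c(2, 0, 0), c(-0.5, 0, 0), sw)
  expect_identical(ev$type, "shell_cross_in")
  expect_identical(ev$boundary, 1.25)
  expect_equal(ev$time, 0.75, tolerance = 1e-14)  # gap 2 -> 1.25 at speed 1
  # oblique approach: compare against the quadratic root computed directly
  r2 <- c(3, 0.6, 0); v2 <- c(-1, 0, 0)
  ev2 <- predict_pair_event(c(0, 0, 0), c(0, 0, 0), r2, v2, sw)
  troot <- polyroot(c(sum(r2^2) - 1.25^2, 2 * sum(r2 * v2), sum(v2^2)))
  texp <- min(Re(troot[abs(Im(troot)) < 1e-9]))
  expect_equal(ev2$time, texp, tolerance = 1e-10)
})

test_that("event resolution conserves momentum and pays the potential step", {
  sw <- make_spec("sw", list(lambda = 1.25, epsilon = 1))
  # equal-mass head-on core collision exchanges velocities
  res <- resolve_event(c(1, 0, 0), c(-1, 0, 0), c(1, 0, 0),
                       1, "core_collision", sw)
  expect_equal(res$v1, c(1, 0, 0), tolerance = 1e-14)
  expect_equal(res$v2, c(-1, 0, 0), tolerance = 1e-14)
  # capture with du = -1 and v_r^2 = 1: outgoing v_r'^2 = 1 + 4 (mu = 1/2)
  res2 <- resolve_event(c(1.25, 0, 0), c(-1, 0, 0), c(0, 0, 0),
                        1.25, "shell_cross_in", sw)
  vr_out <- sum((res2$v1 - res2$v2) * c(1, 0, 0))
  expect_equal(vr_out^2, 5, tolerance = 1e-12)
  expect_identical(res2$outcome, "shell_cross_in")
  # escape attempt with (mu/2) v_r^2 <= du bounces elastically
  res3 <- resolve_event(c(1.25, 0, 0), c(0.5, 0, 0), c(0, 0, 0),
                        1.25, "shell_cross_out", sw)
  expect_identical(res3$outcome, "bounce")
  vr3 <- sum((res3$v1 - res3$v2) * c(1, 0, 0))
  expect_equal(vr3, -0.5, tolerance = 1e-14)
  expect_equal(sum(res3$v1^2) + sum(res3$v2^2), 0.25, tolerance = 1e-14)
})

test_that("random events conserve momentum exactly and energy to machine precision", {
  dsw <- make_spec("double_sw", list(boundaries = c(1.125, 1.25),
                                     depths = c(-1.0, -0.5)))
  set.seed(99)
  u_at <- function(r) evaluate_potential(dsw, r)
  for (i in 1:60) {
    b <- sample(c(1.125, 1.25), 1)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    dr <- b * n
    v1 <- rnorm(3); v2 <- rnorm(3)
    vr <- sum((v1 - v2) * n)
    kind <- if (vr < 0) "shell_cross_in" else "shell_cross_out"
    res <- resolve_event(dr, v1, v2, b, kind, dsw)
    expect_equal(res$v1 + res$v2, v1 + v2, tolerance = 1e-14)
    du <- if (res$outcome == "bounce") 0 else {
      if (kind == "shell_cross_in") u_at(b) - u_at(b * (1 + 1e-9))
      else u_at(b * (1 + 1e-9)) - u_at(b)
    }
    ke0 <- (sum(v1^2) + sum(v2^2)) / 2
    ke1 <- (sum(res$v1^2) + sum(res$v2^2)) / 2
    expect_equal(ke1 - ke0, -du, tolerance = 1e-12)
  }
})
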