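test_that("state constructor enforces the occupancy simplex", {
  expect_silent(tf_state(0.25, 0.25, 0.25, 0.25))
  expect_error(tf_state(0.5, 0.5, 0.5, -0.5), "\\[0, 1\\]")
  expect_error(tf_state(0.5, 0.3, 0.3, 0.3), "sum to 1")
})

test_that("the right-hand side matches direct substitution and conserves mass", {
  k <- c(kBC = 1.7, kCB = 2, kCM1 = 3, kM1C = 4, kM1M2 = 5, kM2M1 = 6, kM2C = 7)
  d <- ode_rhs(tf_state(0, 1, 0, 0), k)
  expect_equal(d[["C"]], -5)              # -(kCB + kCM1) C
  expect_equal(d[["M1"]], 3)
  d <- ode_rhs(tf_state(1, 0, 0, 0), k)   # single-source flux out of B
  expect_equal(d[["C"]], 1.7)
  expect_equal(d[["M1"]], 0)
  expect_equal(d[["M2"]], 0)
  set.seed(5)
  for (i in 1:20) {
    d <- ode_rhs(random_state(), k)
    expect_equal(sum(d), 0)
  }
})

test_that("zero rates give a constant trajectory", {
  p <- tf_params(kBC0 = 0, kBC_Ca2 = 0, kCB0 = 0, kCB_Ca2 = 0, fCM1_0 = 0,
                 fM1C_0 = 0, kM1M2 = 0, kM2M1 = 0, kM2C = 0, pCa50 = 5.6,
                 u1 = 1, u2 = 1, z1 = 1, z2 = 1, v = 1, w = 1,
                 alpha = 1, alpha_bar = 1, beta = 1, beta_bar = 1)
  tr <- integrate_model(tf_state(0.4, 0.3, 0.2, 0.1), p, 5.6, t_end = 0.1)
  expect_true(all(abs(tr$C - 0.3) < 1e-14))
  expect_true(all(abs(tr$M2 - 0.1) < 1e-14))
})

test_that("occupancies stay conserved along trajectories", {
  p <- fixture_params("murine", 2)
  tr <- integrate_model(tf_state(1, 0, 0, 0), p, 4.5, t_end = 0.5)
  expect_true(all(abs(rowSums(tr[, c("B", "C", "M1", "M2")]) - 1) < 1e-8))
  expect_true(all(tr[, -1] > -1e-8 & tr[, -1] < 1 + 1e-8))
})

test_that("halving the step does not change the trajectory endpoint", {
  p <- fixture_params("murine", 8)
  tr1 <- integrate_model(tf_state(1, 0, 0, 0), p, 5.6, t_end = 0.3)
  tr2 <- integrate_model(tf_state(1, 0, 0, 0), p, 5.6, t_end = 0.3,
                         dt = attr(tr1, "dt") / 2)
  expect_lt(max(abs(tail(tr1, 1)[, -1] - tail(tr2, 1)[, -1])), 1e-8)
  trc <- integrate_model(tf_state(1, 0, 0, 0), p, 5.6, t_end = 0.3,
                         check_dt = TRUE)
  expect_lt(max(abs(tail(trc, 1)[, -1] - tail(tr1, 1)[, -1])), 1e-7)
})

test_that("long integration lands on the steady state", {
  p <- fixture_params("murine", 1)
  tr <- integrate_model(tf_state(1, 0, 0, 0), p, 4.5, t_end = 30)
  ss <- steady_state(p, 4.5)
  expect_lt(max(abs(unlist(tail(tr, 1)[, -1]) - ss)), 1e-6)
})

test_that("stiff rate scales integrate stably with the automatic step", {
  p <- fixture_params("porcine", 1)     # closed-to-blocked reference ~5.9e3/s
  # stiffness peaks at low calcium, where kCB is not suppressed
  expect_lt(stable_dt(p, 7.0), 2e-5)
  tr <- integrate_model(tf_state(1, 0, 0, 0), p, 4.5, t_end = 0.05)
  expect_true(all(is.finite(unlist(tr))))
  expect_true(all(abs(rowSums(tr[, -1]) - 1) < 1e-8))
  # a grossly oversized step is rejected even after halving retries
  expect_error(integrate_model(tf_state(1, 0, 0, 0), p, 4.5, t_end = 0.05,
                               dt = 1), "unstable")
})

test_that("steady states are conserved, reproducible from any start, and
           agree with the algebraic root-finding oracle", {
  p <- fixture_params("murine", 8)
  s1 <- steady_state(p, 5.6)
  expect_equal(sum(s1), 1, tolerance = 1e-9)
  s2 <- steady_state(p, 5.6, init = tf_state(0, 1, 0, 0))
  s3 <- steady_state(p, 5.6, init = tf_state(0.25, 0.25, 0.25, 0.25))
  expect_lt(max(abs(s1 - s2)), 1e-6)    # no multistability at these params
  expect_lt(max(abs(s1 - s3)), 1e-6)
  for (pca in c(6.1, 4.5)) {
    ours <- steady_state(p, pca)
    oracle <- oracle_steady(p, pca)
    expect_lt(max(abs(ours - oracle)), 1e-6)
  }
})

test_that("equilibrium force rises monotonically with calcium without
           cooperativity", {
  p <- fixture_params("murine", 1)
  grid <- seq(7, 4.5, by = -0.25)
  m2 <- vapply(grid, function(pc) steady_state(p, pc)[["M2"]], numeric(1))
  expect_true(all(diff(m2) >= -1e-10))
})

test_that("non-convergence inside the time cap is reported with the residual", {
  p <- fixture_params("murine", 1)
  expect_error(steady_state(p, 4.5, t_max = 0.01), "no steady state")
})

test_that("the fixed-step integrator tracks an adaptive multistep solver", {
  p <- fixture_params("murine", 8)
  y0 <- c(C = 0, M1 = 0, M2 = 0)
  rhs_ds <- function(t, y, parms)
    list(oracle_rhs(y, p, 4.5))
  times <- seq(0, 0.5, by = 0.01)
  ref <- deSolve::lsoda(y0, times, rhs_ds, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  tr <- integrate_model(tf_state(1, 0, 0, 0), p, 4.5, t_end = 0.5,
                        sample_dt = 0.01)
  ours <- tr[match(round(times, 10), round(tr$t, 10)), ]
  expect_lt(max(abs(ours$M2 - ref[, "M2"])), 1e-7)
  expect_lt(max(abs(ours$C - ref[, "C"])), 1e-7)
})
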