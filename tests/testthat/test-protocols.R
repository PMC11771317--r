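test_that("force-pCa curves normalise at the most acidic point and vanish
           when nothing leaves the blocked state", {
  p <- fixture_params("murine", 2)
  cv <- force_pca_curve(p, c(6.0, 5.6, 4.5))
  expect_equal(cv$rel_force[cv$pCa == 4.5], 1)
  expect_true(all(cv$rel_force >= 0 & cv$rel_force <= 1 + 1e-9))
  p0 <- unclass(p); p0$kBC0 <- 0; p0$kBC_Ca2 <- 0
  p0 <- tf_params(p0)
  cv0 <- force_pca_curve(p0, c(5.8, 4.5))
  expect_true(all(cv0$force == 0))
  expect_true(all(cv0$rel_force == 0))
})

test_that("Hill fitting recovers generating parameters exactly on noise-free
           curves", {
  grid <- seq(6.5, 4.8, by = -0.1)
  for (p50 in c(5.4, 5.65, 5.9))
    for (n in c(1, 2, 4, 6)) {
      h <- hill_fit(hill_curve(grid, p50, n))
      expect_equal(h$pCa50, p50, tolerance = 1e-6)
      expect_equal(h$n_hill, n, tolerance = 1e-6)
      # fitted relative force is 0.5 at the fitted midpoint by construction
      expect_equal(1 / (1 + 10^(h$n_hill * 0)), 0.5)
    }
})

test_that("Hill fitting rejects degenerate curves", {
  grid <- seq(6.5, 4.8, by = -0.2)
  expect_error(hill_fit(data.frame(pCa = grid, rel_force = 0.7)), "flat")
  expect_error(hill_fit(hill_curve(grid, 5.6, 2)[1:3, ]), "at least 4")
  one_sided <- hill_curve(seq(5.3, 4.8, by = -0.1), 5.9, 3)
  expect_error(hill_fit(one_sided), "both sides")
})

test_that("the slack-restretch protocol matches the analytic solution of a
           linear (non-cooperative) model", {
  p <- fixture_params("murine", 1)
  pca <- 4.5
  kt <- ktr_protocol(p, pca)
  # all cooperative coefficients are 1: the system is linear, solve it exactly
  eq <- oracle_linear_equilibrium(p, pca)
  dslack <- 1e-8
  slack_eq <- oracle_linear_equilibrium(
    p, pca, fCM1_ref = dslack * p$fM1C_0 / (1 - dslack))
  F_ss <- eq[["M2"]]; F_resid <- slack_eq[["M2"]]
  target <- F_resid + 0.5 * (F_ss - F_resid)
  t_half <- uniroot(function(t)
    oracle_linear_m2(p, pca, unname(slack_eq[c("C", "M1", "M2")]), t) - target,
    c(1e-6, 1), tol = 1e-12)$root
  expect_equal(kt$F_ss, F_ss, tolerance = 1e-6)
  expect_equal(kt$F_resid, F_resid, tolerance = 1e-4)
  expect_equal(kt$ktr, log(2) / t_half, tolerance = 5e-3)
})

test_that("ktr results satisfy their structural invariants", {
  p <- fixture_params("murine", 2)
  kt <- ktr_protocol(p, 5.7)
  expect_gte(kt$F_ss, kt$F_resid)
  expect_gte(kt$F_resid, 0)
  expect_gt(kt$ktr, 0)
  expect_equal(kt$ktr, log(2) / kt$t_half)
  expect_equal(kt$delta_normal, p$fCM1_0 / (p$fCM1_0 + p$fM1C_0))
  # transient starts at the residual-force state and rises through the target
  expect_equal(kt$transient$M2[1], kt$F_resid, tolerance = 1e-6)
  expect_gte(max(kt$transient$M2), kt$F_resid + 0.5 * (kt$F_ss - kt$F_resid))
})

test_that("ktr is insensitive to the exact slack duty cycle", {
  p <- fixture_params("murine", 2)
  k8 <- ktr_protocol(p, 4.5, delta_slack = 1e-8)$ktr
  k9 <- ktr_protocol(p, 4.5, delta_slack = 1e-9)$ktr
  expect_lt(abs(k8 - k9) / k8, 1e-3)
})

test_that("degenerate protocol configurations are refused", {
  p <- fixture_params("murine", 2)
  expect_error(ktr_protocol(p, 4.5, delta_slack = 0.9), "delta_slack")
  expect_error(ktr_protocol(p, 4.5, delta_slack = 0), "delta_slack")
})

test_that("relative ktr normalises at maximal activation", {
  cv <- data.frame(pCa = c(6.1, 5.8, 4.5), ktr = c(2, 2, 2))
  expect_equal(relative_ktr(cv)$rel_ktr, c(1, 1, 1))
  cv2 <- data.frame(pCa = c(6.1, 5.8), ktr = c(1, 2))
  expect_error(relative_ktr(cv2), "maximal-activation")
})

test_that("activation and recruitment factors reduce to reference ratios
           without cooperativity and reject an undefined K", {
  p1 <- fixture_params("murine", 1)
  set.seed(7)
  for (i in 1:10) {
    dq <- derived_quantities(p1, random_state())
    expect_equal(dq$K, p1$kBC0 / p1$kCB0)      # state-independent
    expect_equal(dq$N, p1$fCM1_0 / p1$fM1C_0)
  }
  s <- tf_state(0.1, 0.5, 0.2, 0.2)
  dq <- derived_quantities(p1, s)
  expect_equal(dq$lam_cyc, 0.9)
  expect_equal(dq$lam_cyc_M2, 0.2 / 0.9)
  bad <- unclass(p1); bad$kCB0 <- 0
  expect_error(derived_quantities(tf_params(bad), s), "kCB0 = 0")
})

test_that("an identity sweep reproduces the unswept model", {
  p <- fixture_params("murine", 8)
  sw <- sensitivity_sweep(p, "u2", p$u2, pCa_list = c(4.5))
  eq <- steady_state(p, 4.5)
  kt <- ktr_protocol(p, 4.5, eq = eq)
  dq <- derived_quantities(p, eq)
  expect_equal(sw$M2, eq[["M2"]], tolerance = 1e-10)
  expect_equal(sw$ktr, kt$ktr, tolerance = 1e-10)
  expect_equal(sw$N, dq$N, tolerance = 1e-10)
  expect_equal(sw$rel_ktr, 1)
})
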