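test_that("calcium saturation ratio behaves as a concentration-space sigmoid", {
  expect_identical(ca_ratio(5.64, 5.64), 0.5)
  expect_lt(ca_ratio(12, 5.64), 1e-6)                 # zero-calcium limit
  expect_equal(ca_ratio(4.5, 5.64), 0.932449971, tolerance = 1e-8)
  grid <- seq(7, 4.5, by = -0.1)                      # pCa down, ratio up
  expect_true(all(diff(ca_ratio(grid, 5.65)) > 0))
  expect_error(ca_ratio(NA_real_, 5.6), "finite")
  expect_error(ca_ratio(4.5, Inf), "finite")
})

test_that("calcium-dependent baseline rate interpolates its two references", {
  expect_identical(baseline_rate(0.0166, 0.4370, 0), 0.0166)
  expect_identical(baseline_rate(0.0166, 0.4370, 1), 0.4370)
  expect_equal(baseline_rate(2.3633, 0.3979, 0.5), 1.3806)
  expect_error(baseline_rate(1, 2, 1.5))
})

test_that("RU-RU cooperative factors match direct arithmetic and reduce to 1", {
  # no cooperativity, and closed-reference neighbors
  expect_equal(ru_factor_fwd(0.3, 0.4, 1, 1), 1)
  expect_equal(ru_factor_rev(0.3, 0.4, 1, 1), 1)
  expect_equal(ru_factor_fwd(0, 0, 5, 9), 1)
  expect_equal(ru_factor_rev(0, 0, 5, 9), 1)
  # equilibrium fractions of the murine unitary RU-RU regime
  expect_equal(ru_factor_fwd(0.0362, 0.4479, 1.0, 2.2208), 2.392578856,
               tolerance = 1e-8)
  expect_equal(ru_factor_rev(0.0362, 0.4479, 1.0, 2.2208), 0.568190436,
               tolerance = 1e-8)
  expect_warning(ru_factor_fwd(0.2, 0.2, 0.8, 1), "anti-cooperative")
})

test_that("crossbridge-mediated factors match direct arithmetic", {
  expect_equal(xb_factor_fwd(0.7, 1), 1)
  expect_equal(xb_factor_rev(0.7, 1), 1)
  expect_equal(xb_factor_fwd(0, 3), 1)
  expect_equal(xb_factor_rev(0, 3), 1)
  expect_equal(xb_factor_fwd(0.5, 2), 3.456404939, tolerance = 1e-8)
  expect_equal(xb_factor_rev(0.5, 2), 0.4677735414, tolerance = 1e-8)
})

test_that("cooperative factors are perfect squares, hence non-negative", {
  set.seed(11)
  for (i in 1:50) {
    s <- random_state()
    lamB <- s[["B"]]; lamM <- s[["M1"]] + s[["M2"]]
    a <- runif(2, 1, 20)
    expect_gte(ru_factor_fwd(lamB, lamM, a[1], a[2]), 0)
    expect_gte(ru_factor_rev(lamB, lamM, a[1], a[2]), 0)
    expect_gte(xb_factor_fwd(s[["M2"]], a[1]), 0)
    expect_gte(xb_factor_rev(s[["M2"]], a[1]), 0)
    expect_lte(xb_factor_rev(s[["M2"]], a[1]), 1)   # c >= 1 slows the reverse
  }
})

test_that("with unit cooperative coefficients every rate is its baseline,
           for any interaction factors", {
  set.seed(21)
  p1 <- fixture_params("murine", 1)
  for (i in 1:100) {
    p <- unclass(p1)
    p[c("alpha", "alpha_bar", "beta", "beta_bar")] <- as.list(runif(4))
    class(p) <- "tf_params"
    s <- random_state()
    pca <- runif(1, 4.5, 6.5)
    k <- transition_rates(s, p, pca)
    r <- ca_ratio(pca, p$pCa50)
    expect_equal(k[["kBC"]], baseline_rate(p$kBC0, p$kBC_Ca2, r))
    expect_equal(k[["kCB"]], baseline_rate(p$kCB0, p$kCB_Ca2, r))
    expect_equal(k[["kCM1"]], p$fCM1_0)
    expect_equal(k[["kM1C"]], p$fM1C_0)
  }
})

test_that("the all-closed state collapses every factor to the reference rate", {
  p <- fixture_params("murine", 2)      # strong u2, RU-RU only
  s <- tf_state(B = 0, C = 1, M1 = 0, M2 = 0)
  k <- transition_rates(s, p, 5.8)
  r <- ca_ratio(5.8, p$pCa50)
  expect_equal(k[["kBC"]], baseline_rate(p$kBC0, p$kBC_Ca2, r))
  expect_equal(k[["kCB"]], baseline_rate(p$kCB0, p$kCB_Ca2, r))
  expect_equal(k[["kCM1"]], p$fCM1_0)
})

test_that("interaction factors interpolate between pure RU and pure XB forms", {
  set.seed(31)
  for (i in 1:25) {
    base <- random_params()
    s <- random_state()
    lamB <- s[["B"]]; lamM <- s[["M1"]] + s[["M2"]]; M2 <- s[["M2"]]
    pca <- 5.7
    r <- ca_ratio(pca, base$pCa50)
    fBC0 <- baseline_rate(base$kBC0, base$kBC_Ca2, r)
    fCM1 <- base$fCM1_0
    for (a in c(0, 1)) {
      p <- unclass(base)
      p[c("alpha", "alpha_bar", "beta", "beta_bar")] <- as.list(rep(a, 4))
      class(p) <- "tf_params"
      k <- transition_rates(s, p, pca)
      if (a == 1) {
        expect_equal(k[["kBC"]],
                     fBC0 * ru_factor_fwd(lamB, lamM, p$u1, p$u2))
        expect_equal(k[["kCM1"]],
                     fCM1 * ru_factor_fwd(lamB, lamM, p$z1, p$z2))
      } else {
        expect_equal(k[["kBC"]], fBC0 * xb_factor_fwd(M2, p$w))
        expect_equal(k[["kCM1"]], fCM1 * xb_factor_fwd(M2, p$v))
      }
    }
  }
})

test_that("compiled and interpreted right-hand sides agree", {
  set.seed(41)
  for (i in 1:25) {
    p <- random_params()
    s <- random_state()
    pca <- runif(1, 4.5, 6.5)
    r_rhs <- ode_rhs(s, transition_rates(s, p, pca))
    c_rhs <- thinfil:::cpp_rhs(unname(s[c("C", "M1", "M2")]),
                               thinfil:::cpp_pars(p, pca))
    expect_equal(unname(r_rhs[c("C", "M1", "M2")]), c_rhs, tolerance = 1e-12)
  }
})
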