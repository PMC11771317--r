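## Independent oracles and small generators shared across the test files.

## random point on the 4-state simplex
random_state <- function() {
  x <- -log(runif(4))
  x <- x / sum(x)
  tf_state(B = x[1], C = x[2], M1 = x[3], M2 = x[4])
}

## random valid parameter set (cooperative regime)
random_params <- function(coop_max = 3) {
  tf_params(
    kBC0 = runif(1, 0, 2), kBC_Ca2 = runif(1, 0, 50),
    kCB0 = runif(1, 0, 50), kCB_Ca2 = runif(1, 0, 10),
    fCM1_0 = runif(1, 10, 80), fM1C_0 = runif(1, 10, 80),
    kM1M2 = runif(1, 5, 60), kM2M1 = runif(1, 5, 60), kM2C = runif(1, 5, 60),
    pCa50 = runif(1, 5.5, 5.8),
    u1 = runif(1, 1, coop_max), u2 = runif(1, 1, coop_max),
    z1 = runif(1, 1, coop_max), z2 = runif(1, 1, coop_max),
    v = runif(1, 1, coop_max), w = runif(1, 1, coop_max),
    alpha = runif(1), alpha_bar = runif(1),
    beta = runif(1), beta_bar = runif(1))
}

## Hand-coded copy of the model equations, kept independent of the package
## implementation: rates from the published expressions, derivatives of
## (C, M1, M2) with B recovered from conservation. No validation on purpose,
## so root finders may step off the simplex while iterating.
oracle_rhs <- function(y, p, pCa, fCM1_ref = NULL) {
  C <- y[1]; M1 <- y[2]; M2 <- y[3]; B <- 1 - C - M1 - M2
  lamM <- M1 + M2
  r <- 10^(p$pCa50 - pCa) / (1 + 10^(p$pCa50 - pCa))
  fBC0 <- p$kBC0 + (p$kBC_Ca2 - p$kBC0) * r
  fCB0 <- p$kCB0 + (p$kCB_Ca2 - p$kCB0) * r
  fCM1 <- if (is.null(fCM1_ref)) p$fCM1_0 else fCM1_ref
  kBC <- fBC0 * (p$alpha * (1 - B * (1 - 1 / p$u1) + lamM * (p$u2 - 1))^2 +
                   (1 - p$alpha) * (1 + M2 * (exp(p$w - 1) - 1))^2)
  kCB <- fCB0 * (p$alpha_bar * (1 + B * (p$u1 - 1) - lamM * (1 - 1 / p$u2))^2 +
                   (1 - p$alpha_bar) * (1 + M2 * (exp(1 - p$w) - 1))^2)
  kCM1 <- fCM1 * (p$beta * (1 - B * (1 - 1 / p$z1) + lamM * (p$z2 - 1))^2 +
                    (1 - p$beta) * (1 + M2 * (exp(p$v - 1) - 1))^2)
  kM1C <- p$fM1C_0 * (p$beta_bar * (1 + B * (p$z1 - 1) - lamM * (1 - 1 / p$z2))^2 +
                        (1 - p$beta_bar) * (1 + M2 * (exp(1 - p$v) - 1))^2)
  c(kBC * B + p$kM2C * M2 + kM1C * M1 - (kCB + kCM1) * C,
    kCM1 * C + p$kM2M1 * M2 - (kM1C + p$kM1M2) * M1,
    p$kM1M2 * M1 - (p$kM2C + p$kM2M1) * M2)
}

## algebraic steady-state oracle: Broyden root find of the hand-coded system
oracle_steady <- function(p, pCa, x0 = c(0.3, 0.3, 0.2)) {
  sol <- pracma::fsolve(function(y) oracle_rhs(y, p, pCa), x0, tol = 1e-12)
  y <- sol$x
  c(B = 1 - sum(y), C = y[1], M1 = y[2], M2 = y[3])
}

## For regimes with all cooperative coefficients at 1 the system is linear,
## dy/dt = A y + b: analytic equilibrium and transient via eigendecomposition.
oracle_linear_system <- function(p, pCa, fCM1_ref = NULL) {
  r <- 10^(p$pCa50 - pCa) / (1 + 10^(p$pCa50 - pCa))
  kBC <- p$kBC0 + (p$kBC_Ca2 - p$kBC0) * r
  kCB <- p$kCB0 + (p$kCB_Ca2 - p$kCB0) * r
  kCM1 <- if (is.null(fCM1_ref)) p$fCM1_0 else fCM1_ref
  kM1C <- p$fM1C_0
  A <- rbind(
    c(-(kBC + kCB + kCM1), kM1C - kBC, p$kM2C - kBC),
    c(kCM1, -(kM1C + p$kM1M2), p$kM2M1),
    c(0, p$kM1M2, -(p$kM2C + p$kM2M1)))
  list(A = A, b = c(kBC, 0, 0))
}

oracle_linear_equilibrium <- function(p, pCa, fCM1_ref = NULL) {
  sys <- oracle_linear_system(p, pCa, fCM1_ref)
  y <- solve(sys$A, -sys$b)
  c(B = 1 - sum(y), C = y[1], M1 = y[2], M2 = y[3])
}

## y(t) = eq + V exp(Lambda t) V^-1 (y0 - eq), evaluated for M2
oracle_linear_m2 <- function(p, pCa, y0, t) {
  sys <- oracle_linear_system(p, pCa)
  eq <- solve(sys$A, -sys$b)
  ev <- eigen(sys$A)
  cvec <- solve(ev$vectors, y0 - eq)
  vapply(t, function(tt)
    Re((ev$vectors %*% (cvec * exp(ev$values * tt)))[3] + eq[3]), numeric(1))
}

## exact Hill curve generator
hill_curve <- function(pCa, pCa50, n) {
  data.frame(pCa = pCa, rel_force = 1 / (1 + 10^(n * (pCa - pCa50))))
}

fixture_grid <- function() {
  list(murine1 = fixture_params("murine", 1),
       murine2 = fixture_params("murine", 2),
       murine8 = fixture_params("murine", 8),
       porcine1 = fixture_params("porcine", 1),
       porcine2 = fixture_params("porcine", 2),
       porcine8 = fixture_params("porcine", 8))
}
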