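## State container, ODE right-hand side, fixed-step RK4 integration and the
## integrated-to-equilibrium steady-state solver.

#' Construct / validate a state vector
#'
#' A state gives the fractional occupancies of the four states: blocked (B),
#' closed (C), strongly bound pre-power-stroke (M1) and force-generating
#' (M2). Occupancies must lie in \[0, 1\] and sum to 1 (the total pool of
#' actin-myosin sites is normalised to 1).
#'
#' @param B,C,M1,M2 occupancies, or a single named vector/list in `B`.
#' @param tol tolerance on the conservation sum.
#' @return named numeric vector of class-less c(B, C, M1, M2).
#' @examples
#' tf_state(B = 1, C = 0, M1 = 0, M2 = 0)
#' @export
tf_state <- function(B, C = NULL, M1 = NULL, M2 = NULL, tol = 1e-9) {
  if (is.null(C) && (is.list(B) || length(B) == 4L)) {
    x <- unlist(B)[c("B", "C", "M1", "M2")]
  } else {
    x <- c(B = B, C = C, M1 = M1, M2 = M2)
  }
  if (any(is.na(x))) stop("state needs all of B, C, M1, M2")
  if (any(x < -tol) || any(x > 1 + tol))
    stop("state occupancies must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop("state occupancies must sum to 1 (got ", format(sum(x)), ")")
  x
}

## pack Ca-evaluated parameters for the C++ integrator
cpp_pars <- function(params, pCa, fCM1_ref = NULL) {
  r <- ca_ratio(pCa, params$pCa50)
  c(baseline_rate(params$kBC0, params$kBC_Ca2, r),
    baseline_rate(params$kCB0, params$kCB_Ca2, r),
    if (is.null(fCM1_ref)) params$fCM1_0 else fCM1_ref,
    params$fM1C_0, params$kM1M2, params$kM2M1, params$kM2C,
    params$u1, params$u2, params$z1, params$z2, params$v, params$w,
    params$alpha, params$alpha_bar, params$beta, params$beta_bar)
}

#' Stable integration step
#'
#' Fixed-step RK4 time step: `min(dt_max, cfl / k_max)` where `k_max` bounds
#' the largest transition rate attainable anywhere on the state simplex,
#' including worst-case cooperative amplification (the RU forward factor is
#' at most `u2^2`, the XB forward factor at most `exp(2(v-1))`, and so on).
#' The default safety fraction 0.1 sits far inside the RK4 linear stability
#' limit of ~2.8.
#'
#' @param params a `tf_params`.
#' @param pCa working calcium level.
#' @param fCM1_ref optional closed-open reference override.
#' @param dt_max upper cap on the step (s).
#' @param cfl safety fraction of the inverse fastest rate.
#' @return time step in seconds.
#' @export
stable_dt <- function(params, pCa, fCM1_ref = NULL, dt_max = 1e-4, cfl = 0.1) {
  p <- params
  r <- ca_ratio(pCa, p$pCa50)
  fBC0 <- baseline_rate(p$kBC0, p$kBC_Ca2, r)
  fCB0 <- baseline_rate(p$kCB0, p$kCB_Ca2, r)
  fCM1 <- if (is.null(fCM1_ref)) p$fCM1_0 else fCM1_ref
  amp_fwd <- function(a1, a2) max(1, a2^2, 1 / a1^2)
  amp_rev <- function(a1, a2) max(1, a1^2, 1 / a2^2)
  amp_xf  <- function(c) max(1, exp(2 * (c - 1)))
  amp_xr  <- function(c) max(1, exp(2 * (1 - c)))
  kmax <- max(
    fBC0 * (p$alpha * amp_fwd(p$u1, p$u2) + (1 - p$alpha) * amp_xf(p$w)),
    fCB0 * (p$alpha_bar * amp_rev(p$u1, p$u2) + (1 - p$alpha_bar) * amp_xr(p$w)),
    fCM1 * (p$beta * amp_fwd(p$z1, p$z2) + (1 - p$beta) * amp_xf(p$v)),
    p$fM1C_0 * (p$beta_bar * amp_rev(p$z1, p$z2) + (1 - p$beta_bar) * amp_xr(p$v)),
    p$kM1M2, p$kM2M1, p$kM2C)
  min(dt_max, cfl / max(kmax, 1e-12))
}

#' ODE right-hand side
#'
#' Time derivatives of the four occupancies at fixed transition rates. C, M1
#' and M2 follow their balance equations; dB/dt is recovered from
#' conservation, so the four derivatives sum to zero exactly.
#'
#' @param state a state vector, see [tf_state()].
#' @param rates named rate vector from [transition_rates()].
#' @return named derivative vector `c(B, C, M1, M2)` in 1/s.
#' @export
ode_rhs <- function(state, rates) {
  s <- tf_state(state)
  k <- rates
  dC  <- k[["kBC"]] * s[["B"]] + k[["kM2C"]] * s[["M2"]] +
    k[["kM1C"]] * s[["M1"]] - (k[["kCB"]] + k[["kCM1"]]) * s[["C"]]
  dM1 <- k[["kCM1"]] * s[["C"]] + k[["kM2M1"]] * s[["M2"]] -
    (k[["kM1C"]] + k[["kM1M2"]]) * s[["M1"]]
  dM2 <- k[["kM1M2"]] * s[["M1"]] - (k[["kM2C"]] + k[["kM2M1"]]) * s[["M2"]]
  c(B = -(dC + dM1 + dM2), C = dC, M1 = dM1, M2 = dM2)
}

## shared driver around the compiled RK4 kernel, with halving retries on
## detected instability
run_rk4 <- function(init, params, pCa, dt, t_max, ss_tol = -1, ss_run = 100,
                    record_dt = -1, stop_m2 = -1, max_halvings = 6) {
  y0 <- init[c("C", "M1", "M2")]
  pars <- cpp_pars(params, pCa,
                   fCM1_ref = attr(params, "fCM1_ref", exact = TRUE))
  for (h in 0:max_halvings) {
    out <- cpp_rk4(y0, pars, dt, t_max, ss_tol, ss_run, record_dt, stop_m2)
    if (!out$unstable) {
      out$dt <- dt
      return(out)
    }
    dt <- dt / 2
  }
  stop("integration unstable even after ", max_halvings,
       " step halvings; try a smaller dt (last tried ", format(dt), " s)")
}

traj_frame <- function(out) {
  st <- out$states
  data.frame(t = out$t, B = 1 - rowSums(st), C = st[, 1],
             M1 = st[, 2], M2 = st[, 3])
}

#' Integrate the model over time
#'
#' Fixed-step fourth-order Runge-Kutta integration of the three balance
#' equations (C, M1, M2), with B recovered from conservation at every step.
#' If `check_dt` is set, the integration is repeated with a halved step until
#' the terminal states of two successive refinements agree within
#' `check_tol` per component.
#'
#' @param init initial state, see [tf_state()].
#' @param params a `tf_params`.
#' @param pCa working calcium level.
#' @param t_end duration (s).
#' @param dt step (s); default from [stable_dt()].
#' @param sample_dt trajectory sampling interval (s); defaults to
#'   `max(dt, t_end/2000)`.
#' @param check_dt logical; refine the step until converged.
#' @param check_tol per-component agreement tolerance for `check_dt`.
#' @return data frame with columns `t`, `B`, `C`, `M1`, `M2`, of class
#'   `tf_trajectory`; the step used is in `attr(, "dt")`.
#' @examples
#' p <- fixture_params("murine", 2)
#' tr <- integrate_model(tf_state(1, 0, 0, 0), p, pCa = 4.5, t_end = 0.5)
#' @export
integrate_model <- function(init, params, pCa, t_end, dt = NULL,
                            sample_dt = NULL, check_dt = FALSE,
                            check_tol = 1e-8) {
  init <- tf_state(init)
  stopifnot(t_end > 0)
  if (is.null(dt)) dt <- stable_dt(params, pCa)
  if (dt <= 0) stop("dt must be positive")
  if (is.null(sample_dt)) sample_dt <- max(dt, t_end / 2000)
  out <- run_rk4(init, params, pCa, dt, t_end, record_dt = sample_dt)
  if (check_dt) {
    for (i in 1:10) {
      out2 <- run_rk4(init, params, pCa, out$dt / 2, t_end,
                      record_dt = sample_dt)
      if (max(abs(out2$y_end - out$y_end)) < check_tol) break
      out <- out2
      if (i == 10) stop("step refinement did not converge")
    }
  }
  tr <- traj_frame(out)
  attr(tr, "dt") <- out$dt
  class(tr) <- c("tf_trajectory", "data.frame")
  tr
}

#' Write a trajectory to CSV
#'
#' @param traj a `tf_trajectory` (or any data frame with columns
#'   `t, B, C, M1, M2`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj[, c("t", "B", "C", "M1", "M2")], path, row.names = FALSE)
  invisible(path)
}

#' Steady state of the model
#'
#' Integrates from `init` until the maximal state derivative stays below
#' `tol` (1/s) for 100 consecutive steps, up to a hard cap of `t_max`
#' simulated seconds. The all-blocked state is the default initial
#' condition, matching the zero-force initial conditions of the force
#' redevelopment protocol.
#'
#' @param params a `tf_params`.
#' @param pCa working calcium level.
#' @param init initial state.
#' @param dt step (s); default from [stable_dt()].
#' @param tol steady-state residual tolerance (1/s).
#' @param t_max simulated-time cap (s).
#' @param fCM1_ref optional closed-open reference override (slack phase).
#' @return named equilibrium state `c(B, C, M1, M2)` with attributes
#'   `t` (time needed), `resid` (final residual) and `dt`.
#' @examples
#' steady_state(fixture_params("murine", 2), pCa = 4.5)
#' @export
steady_state <- function(params, pCa, init = tf_state(1, 0, 0, 0), dt = NULL,
                         tol = 1e-10, t_max = 200, fCM1_ref = NULL) {
  init <- tf_state(init)
  if (is.null(dt)) dt <- stable_dt(params, pCa, fCM1_ref = fCM1_ref)
  attr(params, "fCM1_ref") <- fCM1_ref
  out <- run_rk4(init, params, pCa, dt, t_max, ss_tol = tol, ss_run = 100)
  if (!out$converged)
    stop(sprintf(
      "no steady state within %g s (residual %.3g 1/s > tol %.3g)",
      t_max, out$resid, tol))
  y <- out$y_end
  st <- c(B = 1 - sum(y), C = y[1], M1 = y[2], M2 = y[3])
  attr(st, "t") <- out$t_end
  attr(st, "resid") <- out$resid
  attr(st, "dt") <- out$dt
  st
}
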