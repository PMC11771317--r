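## In-silico experiments: force-pCa curves, Hill fits, the slack-restretch
## force-redevelopment (ktr) protocol, derived activation/recruitment factors
## and sensitivity sweeps over cooperative coefficients.

#' Steady-state force-pCa relation
#'
#' Solves the model to equilibrium at each calcium level; isometric force is
#' the equilibrium M2 occupancy. Relative force normalises by the value at
#' the most acidic (numerically lowest, i.e. highest-calcium) pCa in the
#' grid.
#'
#' @param params a `tf_params`.
#' @param pCa_grid calcium levels to probe.
#' @param ... passed to [steady_state()].
#' @return data frame with columns `pCa`, `force` (equilibrium M2) and
#'   `rel_force`.
#' @export
force_pca_curve <- function(params, pCa_grid, ...) {
  stopifnot(length(pCa_grid) >= 1)
  force <- vapply(pCa_grid, function(pc)
    steady_state(params, pc, ...)[["M2"]], numeric(1))
  ref <- force[which.min(pCa_grid)]
  rel <- if (ref > 0) force / ref else {
    if (any(force > 0)) warning("zero force at the reference pCa")
    force * 0
  }
  data.frame(pCa = pCa_grid, force = force, rel_force = rel)
}

#' Fit the Hill equation to a force-pCa curve
#'
#' Least-squares fit of `P/P0 = 1 / (1 + 10^(n (pCa - pCa50)))` to a
#' relative-force curve. Starting values come from a logit-linear regression
#' of the interior points; the fitted curve passes through 0.5 at the fitted
#' pCa50 by construction.
#'
#' @param curve data frame with columns `pCa` and `rel_force` (a
#'   `force_pca_curve()` output works directly).
#' @return an object of class `tf_hill`: list with `pCa50`, `n_hill`, `rss`
#'   and the input `curve` augmented with fitted values.
#' @examples
#' pca <- seq(6.2, 5.0, by = -0.1)
#' curve <- data.frame(pCa = pca, rel_force = 1 / (1 + 10^(2 * (pca - 5.65))))
#' hill_fit(curve)
#' @export
hill_fit <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("pCa", "rel_force") %in% names(curve)))
  d <- curve[is.finite(curve$pCa) & is.finite(curve$rel_force), ]
  if (nrow(d) < 4) stop("need at least 4 finite curve points")
  if (max(d$rel_force) - min(d$rel_force) < 1e-6)
    stop("degenerate (flat) curve: Hill fit is undetermined")
  if (min(d$rel_force) > 0.5 || max(d$rel_force) < 0.5)
    stop("curve must span both sides of half activation")
  inner <- d[d$rel_force > 0.005 & d$rel_force < 0.995, ]
  if (nrow(inner) < 2) inner <- d
  logit <- log10(1 / pmin(pmax(inner$rel_force, 1e-9), 1 - 1e-9) - 1)
  lf <- lm(logit ~ inner$pCa)
  n0 <- max(coef(lf)[[2]], 0.2)
  p0 <- -coef(lf)[[1]] / coef(lf)[[2]]
  # scaleOffset makes the relative-offset criterion usable on zero-residual
  # (noise-free) curves
  fit <- nls(rel_force ~ 1 / (1 + 10^(n * (pCa - p50))), data = d,
             start = list(n = n0, p50 = p0),
             control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  est <- coef(fit)
  out <- list(pCa50 = unname(est[["p50"]]), n_hill = unname(est[["n"]]),
              rss = sum(residuals(fit)^2),
              curve = transform(d, fitted = fitted(fit)))
  class(out) <- "tf_hill"
  out
}

#' @export
print.tf_hill <- function(x, ...) {
  cat(sprintf("Hill fit: pCa50 = %.4f, n = %.3f (rss %.3g, %d points)\n",
              x$pCa50, x$n_hill, x$rss, nrow(x$curve)))
  invisible(x)
}

#' Slack-restretch force-redevelopment protocol
#'
#' Simulates the ktr maneuver as a transient lowering of the crossbridge duty
#' cycle `delta = fCM1_0 / (fCM1_0 + fM1C_0)`: (i) solve the normal-duty
#' equilibrium at `pCa`, giving the steady force `F_ss` (equilibrium M2);
#' (ii) lower the duty cycle to `delta_slack` by scaling the closed-open
#' reference (`fCM1' = delta_slack * fM1C_0 / (1 - delta_slack)`, `fM1C_0`
#' unchanged) and run to steady state, giving the residual force `F_resid`;
#' (iii) restore the duty cycle, integrate from the slack steady state, and
#' locate by linear interpolation the half-rise time `t_half` at which force
#' first reaches `F_resid + 0.5 (F_ss - F_resid)`. Then
#' `ktr = ln(2) / t_half`. The state-dependent cooperative factors keep
#' acting during the slack phase; only the reference rate is lowered.
#'
#' @param params a `tf_params`.
#' @param pCa working calcium level.
#' @param delta_slack slack-phase duty cycle, in (0, normal duty cycle).
#' @param eq optional precomputed normal-duty equilibrium at `pCa` (skips
#'   phase i).
#' @param sample_dt sampling interval of the returned force transient (s).
#' @param dt integration step for all three phases (s); default from
#'   [stable_dt()].
#' @param ... passed to [steady_state()].
#' @return an object of class `tf_ktr`: list with `ktr` (1/s), `t_half` (s),
#'   `F_ss`, `F_resid`, `delta_normal`, `delta_slack` and the recorded
#'   `transient` (data frame `t`, `B`, `C`, `M1`, `M2`).
#' @examples
#' \donttest{
#' ktr_protocol(fixture_params("murine", 2), pCa = 4.5)
#' }
#' @export
ktr_protocol <- function(params, pCa, delta_slack = 1e-8, eq = NULL,
                         sample_dt = 1e-4, dt = NULL, ...) {
  delta_normal <- params$fCM1_0 / (params$fCM1_0 + params$fM1C_0)
  if (delta_slack <= 0 || delta_slack >= delta_normal)
    stop("delta_slack must lie in (0, ", format(delta_normal), ")")
  if (is.null(eq)) eq <- steady_state(params, pCa, dt = dt, ...)
  F_ss <- eq[["M2"]]
  fCM1_slack <- delta_slack * params$fM1C_0 / (1 - delta_slack)
  slack <- steady_state(params, pCa, init = tf_state(eq), dt = dt,
                        fCM1_ref = fCM1_slack, ...)
  F_resid <- slack[["M2"]]
  if (F_ss <= F_resid)
    stop("degenerate protocol: steady force does not exceed residual force")
  target <- F_resid + 0.5 * (F_ss - F_resid)

  if (is.null(dt)) dt <- stable_dt(params, pCa)
  out <- run_rk4(tf_state(slack), params, pCa, dt, t_max = 200,
                 record_dt = sample_dt, stop_m2 = target)
  if (!out$crossed)
    stop("force transient never reached the half-rise target")
  tr <- traj_frame(out)
  n <- nrow(tr)
  t_half <- approx(tr$M2[(n - 1):n], tr$t[(n - 1):n], xout = target,
                   ties = "ordered")$y
  res <- list(ktr = log(2) / t_half, t_half = t_half,
              F_ss = F_ss, F_resid = F_resid,
              delta_normal = delta_normal, delta_slack = delta_slack,
              transient = tr, eq = eq)
  class(res) <- "tf_ktr"
  res
}

#' @export
print.tf_ktr <- function(x, ...) {
  cat(sprintf(
    "ktr = %.4f 1/s (t_half %.4g s; F_ss %.4g, F_resid %.3g, duty %.4g)\n",
    x$ktr, x$t_half, x$F_ss, x$F_resid, x$delta_normal))
  invisible(x)
}

#' Normalise a ktr-pCa curve by its maximal-activation value
#'
#' Divides each ktr by the value at maximal activation (pCa 4.5, the acidic
#' endpoint), which must be present in the curve.
#'
#' @param ktr_curve data frame with columns `pCa` and `ktr`.
#' @param pCa_max the maximal-activation pCa (default 4.5).
#' @return the input with an added `rel_ktr` column.
#' @export
relative_ktr <- function(ktr_curve, pCa_max = 4.5) {
  stopifnot(is.data.frame(ktr_curve),
            all(c("pCa", "ktr") %in% names(ktr_curve)))
  i <- which(abs(ktr_curve$pCa - pCa_max) < 1e-9)
  if (!length(i))
    stop("curve must include the maximal-activation point pCa = ", pCa_max)
  ktr_curve$rel_ktr <- ktr_curve$ktr / ktr_curve$ktr[i[1]]
  ktr_curve
}

#' Activation and recruitment factors at a state
#'
#' The activation factor `K = kBC/kCB` and crossbridge recruitment factor
#' `N = kCM1/kM1C` summarise the thin filament's responsiveness to calcium
#' and to crossbridge binding. They are evaluated with the zero-calcium
#' reference rates (`kBC0/kCB0` and `fCM1_0/fM1C_0`) scaled by the
#' state-dependent ensemble cooperative factors, together with the cycling
#' fraction `lam_cyc = C + M1 + M2` and the force-generating share of the
#' cycling pool `lam_cyc_M2 = M2 / lam_cyc`.
#'
#' @param params a `tf_params`.
#' @param state an (equilibrium) state, see [tf_state()].
#' @return list with `K`, `N`, `lam_cyc`, `lam_cyc_M2`.
#' @export
derived_quantities <- function(params, state) {
  state <- tf_state(state)
  if (params$kCB0 == 0)
    stop("activation factor K is undefined: kCB0 = 0")
  f <- ensemble_factors(state, params)
  lam_cyc <- state[["C"]] + state[["M1"]] + state[["M2"]]
  list(K = params$kBC0 / params$kCB0 * f$fwd_BC / f$rev_CB,
       N = params$fCM1_0 / params$fM1C_0 * f$fwd_CM1 / f$rev_M1C,
       lam_cyc = lam_cyc,
       lam_cyc_M2 = if (lam_cyc > 0) state[["M2"]] / lam_cyc else NA_real_)
}

#' Sweep a cooperative coefficient
#'
#' Re-evaluates equilibrium state fractions, the activation and recruitment
#' factors, ktr and relative ktr while one cooperative coefficient takes a
#' sequence of values, all other parameters held at `base`.
#'
#' @param base a `tf_params`.
#' @param vary one of `"u1"`, `"u2"`, `"z1"`, `"z2"`, `"v"`, `"w"`.
#' @param values coefficient values to probe.
#' @param pCa_list calcium levels; relative ktr is reported when the list
#'   includes the maximal-activation point (pCa 4.5).
#' @param delta_slack slack-phase duty cycle for the ktr protocol.
#' @param ... passed to [steady_state()].
#' @return data frame with one row per (value, pCa): columns `param`,
#'   `value`, `pCa`, `B`, `C`, `M1`, `M2`, `lam_cyc`, `lam_cyc_M2`, `K`,
#'   `N`, `ktr`, `rel_ktr`.
#' @export
sensitivity_sweep <- function(base, vary, values, pCa_list = c(6.1, 4.5),
                              delta_slack = 1e-8, ...) {
  vary <- match.arg(vary, COOP_NAMES)
  rows <- list()
  for (val in values) {
    p <- unclass(base)
    p[[vary]] <- val
    class(p) <- "tf_params"
    validate_params(p, allow_anticooperative = TRUE)
    sub <- lapply(pCa_list, function(pc) {
      eq <- steady_state(p, pc, ...)
      dq <- derived_quantities(p, eq)
      kt <- ktr_protocol(p, pc, delta_slack = delta_slack, eq = eq, ...)
      data.frame(param = vary, value = val, pCa = pc,
                 B = eq[["B"]], C = eq[["C"]], M1 = eq[["M1"]],
                 M2 = eq[["M2"]], lam_cyc = dq$lam_cyc,
                 lam_cyc_M2 = dq$lam_cyc_M2, K = dq$K, N = dq$N,
                 ktr = kt$ktr)
    })
    sub <- do.call(rbind, sub)
    i_max <- which(abs(sub$pCa - 4.5) < 1e-9)
    sub$rel_ktr <- if (length(i_max)) sub$ktr / sub$ktr[i_max[1]] else NA_real_
    rows[[length(rows) + 1L]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
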