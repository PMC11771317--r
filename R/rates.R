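## Transition-rate expressions: calcium activation, near-neighbor cooperative
## factors, and their ensemble mixing.

#' Calcium saturation ratio
#'
#' Fraction `[Ca]/([Ca50] + [Ca])` of the calcium-sensitive component of the
#' blocked-closed rates, computed in concentration space from pCa values.
#' Equals 0.5 exactly at `pCa = pCa50` and decreases strictly with pCa.
#'
#' @param pCa working calcium level, -log10 molar.
#' @param pCa50 calcium level of half saturation, -log10 molar.
#' @return a fraction in \[0, 1\].
#' @examples
#' ca_ratio(5.64, 5.64)  # 0.5
#' @export
ca_ratio <- function(pCa, pCa50) {
  if (!all(is.finite(pCa)) || !all(is.finite(pCa50)))
    stop("pCa and pCa50 must be finite")
  r <- 10^(pCa50 - pCa)
  r / (1 + r)
}

#' Calcium-dependent baseline rate
#'
#' Linear interpolation `k0 + (kCa - k0) * ratio` between the zero-calcium
#' reference `k0` and the saturating-calcium reference `kCa`; used for the
#' blocked-closed rates kBC and kCB.
#'
#' @param k0 zero-calcium reference rate (1/s).
#' @param kCa saturating-calcium reference rate (1/s).
#' @param ratio calcium saturation from [ca_ratio()].
#' @return rate in 1/s.
#' @export
baseline_rate <- function(k0, kCa, ratio) {
  stopifnot(all(ratio >= 0 & ratio <= 1))
  k0 + (kCa - k0) * ratio
}

check_ru_args <- function(lamB, lamM, a1, a2) {
  stopifnot(all(lamB >= 0), all(lamM >= 0), all(lamB + lamM <= 1 + 1e-9))
  if (any(a1 < 1) || any(a2 < 1))
    warning("RU-RU coefficient(s) < 1: anti-cooperative regime")
}

#' RU-RU cooperative factors
#'
#' Mean-field factors by which an RU-RU interaction scales a forward
#' (blocked-to-closed or closed-to-open) or reverse transition rate. With
#' neighbor-state fractions `lamB` (blocked) and `lamM` (open, M1 + M2) the
#' forward factor is `[1 - lamB (1 - 1/a1) + lamM (a2 - 1)]^2` and the
#' reverse factor `[1 + lamB (a1 - 1) - lamM (1 - 1/a2)]^2`. The same
#' operator serves the blocked-closed step (`a1 = u1`, `a2 = u2`) and the
#' closed-open step (`a1 = z1`, `a2 = z2`); both reduce to 1 when
#' `a1 = a2 = 1` or when both neighbors sit in the closed reference state.
#'
#' @param lamB fraction of blocked RUs.
#' @param lamM fraction of open RUs (M1 + M2).
#' @param a1,a2 cooperative coefficients (>= 1 in cooperative regimes;
#'   values below 1 draw a warning).
#' @return a non-negative multiplier (a perfect square).
#' @export
ru_factor_fwd <- function(lamB, lamM, a1, a2) {
  check_ru_args(lamB, lamM, a1, a2)
  (1 - lamB * (1 - 1 / a1) + lamM * (a2 - 1))^2
}

#' @rdname ru_factor_fwd
#' @export
ru_factor_rev <- function(lamB, lamM, a1, a2) {
  check_ru_args(lamB, lamM, a1, a2)
  (1 + lamB * (a1 - 1) - lamM * (1 - 1 / a2))^2
}

#' Crossbridge-mediated cooperative factors
#'
#' Mean-field factors by which force-generating crossbridges (occupancy `M2`)
#' scale a forward or reverse transition: `[1 + M2 (exp(c - 1) - 1)]^2`
#' forward and `[1 + M2 (exp(1 - c) - 1)]^2` reverse. With `c = v` they act
#' on the closed-open step (XB-XB interaction); with `c = w` on the
#' blocked-closed step (XB-RU interaction). Both equal 1 when `c = 1` or
#' `M2 = 0`, and the reverse factor never exceeds 1 for `c >= 1`.
#'
#' @param M2 fraction of force-generating crossbridges, in \[0, 1\].
#' @param c cooperative coefficient (v or w).
#' @return a non-negative multiplier (a perfect square).
#' @export
xb_factor_fwd <- function(M2, c) {
  stopifnot(all(M2 >= 0 & M2 <= 1))
  (1 + M2 * (exp(c - 1) - 1))^2
}

#' @rdname xb_factor_fwd
#' @export
xb_factor_rev <- function(M2, c) {
  stopifnot(all(M2 >= 0 & M2 <= 1))
  (1 + M2 * (exp(1 - c) - 1))^2
}

## the four ensemble bracket factors mixing RU-mediated and XB-mediated terms
ensemble_factors <- function(state, params) {
  lamB <- state[["B"]]
  lamM <- state[["M1"]] + state[["M2"]]
  M2 <- state[["M2"]]
  p <- params
  suppressWarnings(list(
    fwd_BC  = p$alpha * ru_factor_fwd(lamB, lamM, p$u1, p$u2) +
      (1 - p$alpha) * xb_factor_fwd(M2, p$w),
    rev_CB  = p$alpha_bar * ru_factor_rev(lamB, lamM, p$u1, p$u2) +
      (1 - p$alpha_bar) * xb_factor_rev(M2, p$w),
    fwd_CM1 = p$beta * ru_factor_fwd(lamB, lamM, p$z1, p$z2) +
      (1 - p$beta) * xb_factor_fwd(M2, p$v),
    rev_M1C = p$beta_bar * ru_factor_rev(lamB, lamM, p$z1, p$z2) +
      (1 - p$beta_bar) * xb_factor_rev(M2, p$v)
  ))
}

#' State-dependent transition rates
#'
#' Evaluates all seven transition rates of the four-state model at a given
#' state and calcium level. The blocked-closed references are
#' calcium-dependent ([baseline_rate()]); each of kBC, kCB, kCM1 and kM1C is
#' its reference times a convex mixture (weights `alpha`, `alpha_bar`,
#' `beta`, `beta_bar`) of the RU-mediated and XB-mediated cooperative
#' factors; kM1M2, kM2M1 and kM2C are state-independent. With all six
#' cooperative coefficients equal to 1 every rate reduces to its baseline
#' regardless of the interaction factors.
#'
#' @param state named state vector, see [tf_state()].
#' @param params a `tf_params`.
#' @param pCa working calcium level.
#' @param fCM1_ref optional override of the closed-open reference rate,
#'   used internally by the slack-restretch protocol.
#' @return named numeric vector with elements `kBC`, `kCB`, `kCM1`, `kM1C`,
#'   `kM1M2`, `kM2M1`, `kM2C` (1/s).
#' @export
transition_rates <- function(state, params, pCa, fCM1_ref = NULL) {
  state <- tf_state(state)
  r <- ca_ratio(pCa, params$pCa50)
  fBC0 <- baseline_rate(params$kBC0, params$kBC_Ca2, r)
  fCB0 <- baseline_rate(params$kCB0, params$kCB_Ca2, r)
  fCM1 <- if (is.null(fCM1_ref)) params$fCM1_0 else fCM1_ref
  f <- ensemble_factors(state, params)
  c(kBC  = fBC0 * f$fwd_BC,
    kCB  = fCB0 * f$rev_CB,
    kCM1 = fCM1 * f$fwd_CM1,
    kM1C = params$fM1C_0 * f$rev_M1C,
    kM1M2 = params$kM1M2, kM2M1 = params$kM2M1, kM2C = params$kM2C)
}
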