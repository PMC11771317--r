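## Constrained multi-start fitting of the model to contractility data, and
## the S3 surface of the fitted-model object.

#' Root mean squared error
#'
#' @param predicted,observed equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25/2)
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted))
    stop("predicted and observed must have equal, positive length")
  sqrt(mean((predicted - observed)^2))
}

default_template <- function() {
  tf_params(kBC0 = 0.1, kBC_Ca2 = 2, kCB0 = 5, kCB_Ca2 = 1,
            fCM1_0 = 50, fM1C_0 = 50, kM1M2 = 40, kM2M1 = 40, kM2C = 40,
            pCa50 = 5.65, u1 = 1, u2 = 1, z1 = 1, z2 = 1, v = 1, w = 1,
            alpha = 1, alpha_bar = 1, beta = 1, beta_bar = 1)
}

default_bounds <- function(free, spec, rate_upper) {
  b <- matrix(NA_real_, length(free), 2,
              dimnames = list(free, c("lower", "upper")))
  for (nm in free) {
    b[nm, ] <- if (nm %in% RATE_NAMES) c(0, rate_upper)
    else if (nm == "pCa50") c(5.3, 6.0)
    else if (nm %in% rownames(spec$free)) spec$free[nm, ]
    else if (nm %in% COOP_NAMES) c(1, 50)
    else c(0, 1)
  }
  b
}

theta_to_params <- function(theta, free, template, spec) {
  p <- unclass(template)
  p[free] <- as.list(unname(theta))
  class(p) <- "tf_params"
  apply_set_spec(p, spec)
}

model_curves <- function(params, pCa, target, delta_slack,
                         sample_dt = 1e-4, dt = NULL) {
  out <- list()
  if (target %in% c("ktr", "both")) {
    out$ktr <- vapply(pCa, function(pc)
      ktr_protocol(params, pc, delta_slack = delta_slack,
                   sample_dt = sample_dt, dt = dt)$ktr, numeric(1))
  }
  if (target %in% c("force", "both")) {
    out$force <- force_pca_curve(params, pCa, dt = dt)$rel_force
  }
  out
}

#' Fit the cooperative thin-filament model to contractility data
#'
#' Constrained multi-start least-squares estimation of the model parameters
#' from a ktr-pCa (and optionally force-pCa) dataset. The free parameters are
#' by default the 9 reference rate coefficients, pCa50 and whichever
#' cooperative coefficients / interaction factors the chosen regime template
#' leaves free; `free` can restrict estimation to any subset (the rest stay
#' at `init`). Starting points are Latin-hypercube samples of the bound box
#' (plus `init`); each start is refined with box-constrained quasi-Newton
#' (`optim` L-BFGS-B) on the unweighted RMSE between the simulated and
#' observed mean curves, and the best start is returned. The whole procedure
#' is deterministic given `seed`.
#'
#' @param data contractility data frame with columns `pCa`, `force_mean`,
#'   `force_sem`, `ktr_mean`, `ktr_sem`, `n` (see [read_contractility()]).
#' @param set regime template id (1-8) or a `tf_set_spec`.
#' @param target fit the `"ktr"` curve (default), the relative `"force"`
#'   curve, or `"both"` (ktr residuals are then scaled by the maximal
#'   observed ktr so the two blocks are commensurate).
#' @param free character vector of parameter names to estimate; default as
#'   described above.
#' @param init optional `tf_params` giving values for parameters not
#'   estimated and an extra starting point for those that are.
#' @param bounds optional named 2-column matrix (`lower`, `upper`) of bounds
#'   for the free parameters, overriding the defaults.
#' @param n_starts number of Latin-hypercube candidate starts; all are
#'   evaluated, and only the most promising are refined.
#' @param n_refine number of best-ranked candidates polished with the local
#'   optimiser (the `init` point is always polished as well).
#' @param seed integer seed controlling the start sample.
#' @param weight_sem if `TRUE`, residuals are divided by the reported SEM.
#' @param rate_upper default upper bound for free rate coefficients (1/s).
#' @param delta_slack slack-phase duty cycle for simulated ktr.
#' @param sim_dt integration step used when simulating candidate curves
#'   (default: the automatic stable step); a coarser explicit step speeds up
#'   exploratory fits at negligible accuracy cost for the smooth murine-scale
#'   rate regimes.
#' @param control passed to [stats::optim()].
#' @return an object of class `ktr_fit` with components `params` (fitted
#'   `tf_params`), `coefficients` (free-parameter estimates), `rmse`,
#'   `set_spec`, `data`, `target`, `starts` (per-start objective values),
#'   `converged`, `seed`. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' truth <- fixture_params("murine", 2)
#' d <- synth_dataset(truth, pCa_grid = c(6.0, 5.8, 5.6, 4.5),
#'                    force_sem_scale = 0, ktr_sem_scale = 0)
#' fit <- ktr_fit(d, set = 2, free = "u2", init = truth, n_starts = 4)
#' coef(fit)
#' }
#' @export
ktr_fit <- function(data, set = 8, target = c("ktr", "force", "both"),
                    free = NULL, init = NULL, bounds = NULL, n_starts = 32,
                    n_refine = 4, seed = 1, weight_sem = FALSE, rate_upper = 500,
                    delta_slack = 1e-8, sim_dt = NULL,
                    control = list(maxit = 100)) {
  target <- match.arg(target)
  data <- check_contractility(data)
  spec <- if (inherits(set, "tf_set_spec")) set else param_set_spec(set)
  template <- if (is.null(init)) default_template() else init
  template <- apply_set_spec(template, spec)
  if (is.null(free)) free <- c(RATE_NAMES, "pCa50", rownames(spec$free))
  free <- unique(free)
  if (any(free %in% names(spec$fixed)))
    stop("cannot free parameters fixed by the regime template: ",
         paste(intersect(free, names(spec$fixed)), collapse = ", "))
  b <- default_bounds(free, spec, rate_upper)
  if (!is.null(bounds)) b[rownames(bounds), ] <- bounds

  obs_ktr <- data$ktr_mean
  obs_force <- data$force_mean
  ktr_scale <- if (target == "both") max(obs_ktr) else 1
  objective <- function(theta) {
    p <- tryCatch(theta_to_params(theta, free, template, spec),
                  error = function(e) NULL)
    if (is.null(p)) return(1e6)
    cur <- tryCatch(model_curves(p, data$pCa, target, delta_slack, dt = sim_dt),
                    error = function(e) NULL)
    if (is.null(cur)) return(1e6)
    res <- c(
      if (!is.null(cur$ktr)) {
        r <- (cur$ktr - obs_ktr) / ktr_scale
        if (weight_sem) r * ktr_scale / pmax(data$ktr_sem, 1e-9) else r
      },
      if (!is.null(cur$force)) {
        r <- cur$force - obs_force
        if (weight_sem) r / pmax(data$force_sem, 1e-9) else r
      })
    sqrt(mean(res^2))
  }

  ## Latin-hypercube starts, plus the template's own values
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  grid <- lhs::randomLHS(n_starts, length(free))
  starts <- t(apply(grid, 1, function(u) b[, 1] + u * (b[, 2] - b[, 1])))
  if (length(free) == 1L) starts <- t(starts)
  colnames(starts) <- free
  starts <- rbind(starts, unlist(unclass(template)[free]))

  ## stage 1: rank all candidates by a plain objective evaluation (the
  ## least-squares surface is multimodal with narrow basins, so gradient
  ## descent from a poor start routinely jumps across them)
  eval0 <- apply(starts, 1, function(th)
    tryCatch(objective(th), error = function(e) Inf))
  if (all(!is.finite(eval0)))
    stop("all starts failed to produce a finite objective")
  ## stage 2: local polish of the best-ranked candidates, always including
  ## the template/init point (the last row)
  refine_idx <- union(order(eval0)[seq_len(min(n_refine, nrow(starts)))],
                      nrow(starts))
  runs <- lapply(refine_idx, function(i)
    tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = b[, 1], upper = b[, 2], control = control),
      error = function(e) list(par = starts[i, ], value = eval0[i],
                               convergence = 99L)))
  values <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(values)]]
  params <- theta_to_params(best$par, free, template, spec)
  fit <- list(params = params,
              coefficients = setNames(as.numeric(best$par), free),
              rmse = best$value, set_spec = spec, data = data,
              target = target, delta_slack = delta_slack, sim_dt = sim_dt,
              starts = data.frame(start = seq_along(eval0), value = eval0,
                                  refined = seq_along(eval0) %in% refine_idx),
              refined = data.frame(start = refine_idx, value = values),
              converged = best$convergence == 0L,
              n_starts = nrow(starts), seed = seed, free = free, bounds = b)
  class(fit) <- "ktr_fit"
  fit
}

#' @export
print.ktr_fit <- function(x, ...) {
  cat(sprintf("Thin-filament model fit (parameter set %d, target %s)\n",
              x$set_spec$set_id, x$target))
  cat(sprintf("  RMSE %.4f over %d pCa points; %d starts, seed %d\n",
              x$rmse, nrow(x$data), x$n_starts, x$seed))
  cat("  estimates:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.ktr_fit <- function(object, ...) object$coefficients

#' @export
summary.ktr_fit <- function(object, ...) {
  cat(sprintf("Regime: set %d (%s)\n", object$set_spec$set_id,
              object$set_spec$description))
  print(object)
  cat(sprintf("  best/median/worst start objective: %.4g / %.4g / %.4g\n",
              min(object$starts$value), median(object$starts$value),
              max(object$starts$value)))
  cat(sprintf("  converged: %s\n", object$converged))
  invisible(object)
}

#' @export
predict.ktr_fit <- function(object, pCa = NULL, type = c("ktr", "force"), ...) {
  type <- match.arg(type)
  if (is.null(pCa)) pCa <- object$data$pCa
  if (type == "ktr") {
    data.frame(pCa = pCa, ktr = vapply(pCa, function(pc)
      ktr_protocol(object$params, pc, delta_slack = object$delta_slack,
                   dt = object$sim_dt)$ktr, numeric(1)))
  } else {
    force_pca_curve(object$params, pCa, dt = object$sim_dt)
  }
}

#' @export
fitted.ktr_fit <- function(object, ...) {
  type <- if (object$target == "force") "force" else "ktr"
  pr <- predict(object, type = type)
  if (type == "ktr") pr$ktr else pr$rel_force
}

#' @export
residuals.ktr_fit <- function(object, ...) {
  obs <- if (object$target == "force") object$data$force_mean
         else object$data$ktr_mean
  obs - fitted(object)
}

#' @export
plot.ktr_fit <- function(x, ...) {
  d <- x$data
  pr <- predict(x, pCa = seq(max(d$pCa), min(d$pCa), by = -0.05))
  xlim <- rev(range(d$pCa))
  plot(d$pCa, d$ktr_mean, xlim = xlim, pch = 16,
       xlab = "pCa", ylab = expression(italic(k)[tr] ~ (s^-1)), ...)
  arrows(d$pCa, d$ktr_mean - d$ktr_sem, d$pCa, d$ktr_mean + d$ktr_sem,
         angle = 90, code = 3, length = 0.03)
  lines(pr$pCa, pr$ktr, col = "firebrick", lwd = 2)
  legend("topright", c("data (mean +/- SEM)", "model"),
         pch = c(16, NA), lty = c(NA, 1), col = c("black", "firebrick"),
         bty = "n")
  invisible(x)
}

#' @export
simulate.ktr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- object$seed
  d <- object$data
  n_preps <- max(2L, as.integer(round(median(d$n))))
  ## back out relative noise scales from the reported SEMs
  kscale <- median(d$ktr_sem * sqrt(d$n) / pmax(d$ktr_mean, 1e-9))
  fscale <- median(d$force_sem * sqrt(d$n) / pmax(d$force_mean, 1e-9))
  out <- lapply(seq_len(nsim), function(i)
    synth_dataset(object$params, pCa_grid = d$pCa, n_preps = n_preps,
                  force_sem_scale = fscale, ktr_sem_scale = kscale,
                  seed = seed + i - 1L, delta_slack = object$delta_slack))
  if (nsim == 1L) out[[1]] else out
}

#' Compare regime templates on one dataset
#'
#' Fits each requested parameter set to the same data and reports the
#' attained RMSE, enabling the comparison of cooperative regimes (e.g.
#' whether templates lacking the RU-RU interaction fit worse).
#'
#' @param data contractility data frame.
#' @param set_ids regime ids to fit.
#' @param ... passed to [ktr_fit()].
#' @return data frame with columns `set_id` and `rmse`, plus the fits in
#'   `attr(, "fits")`.
#' @export
compare_sets <- function(data, set_ids, ...) {
  fits <- lapply(set_ids, function(s) ktr_fit(data, set = s, ...))
  out <- data.frame(set_id = set_ids,
                    rmse = vapply(fits, `[[`, numeric(1), "rmse"))
  attr(out, "fits") <- fits
  out
}
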