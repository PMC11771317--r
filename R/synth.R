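## Synthetic contractility datasets with known ground truth, emulating the
## mean +/- SEM tables produced by permeabilized-myocardium experiments.

#' Default pCa grid for contractility datasets
#'
#' A grid spanning threshold to maximal activation, including the probe
#' points pCa 6.1 and 4.5 used by the sensitivity analyses.
#'
#' @param species kept for symmetry of the murine/porcine interfaces; both
#'   species use the same default grid.
#' @return numeric vector of pCa values in decreasing order.
#' @export
default_pca_grid <- function(species = c("murine", "porcine")) {
  match.arg(species)
  c(6.2, 6.1, 6.0, 5.9, 5.8, 5.7, 5.6, 5.5, 5.4, 4.5)
}

#' Generate a synthetic contractility dataset
#'
#' Simulates the true relative force-pCa and ktr-pCa curves from a known
#' parameter set, then draws `n_preps` Gaussian pseudo-preparations per pCa
#' with standard deviation proportional to the true value
#' (`sd = scale * true`), reporting per-pCa mean, SEM (`sd/sqrt(n)`) and n —
#' the table shape produced by steady-state mechanical measurements in
#' permeabilized myocardium. Negative draws are clipped at zero and counted.
#' Fully reproducible from `seed`.
#'
#' @param truth a `tf_params` used as ground truth.
#' @param pCa_grid calcium levels.
#' @param n_preps pseudo-preparations per pCa (>= 2).
#' @param force_sem_scale,ktr_sem_scale relative noise SD of a single
#'   preparation for force and ktr (0 gives noise-free means).
#' @param seed integer seed.
#' @param delta_slack slack-phase duty cycle for simulated ktr.
#' @param true_curves optional precomputed list with elements `force` and
#'   `ktr` (vectors along `pCa_grid`); skips the model runs, for repeated
#'   noise realisations of the same truth.
#' @return data frame with columns `pCa`, `force_mean`, `force_sem`,
#'   `ktr_mean`, `ktr_sem`, `n`; attributes `truth`, `true_curves`, `seed`
#'   and `n_clipped`.
#' @examples
#' \donttest{
#' d <- synth_dataset(fixture_params("murine", 2),
#'                    pCa_grid = c(6.0, 5.7, 4.5), n_preps = 6, seed = 7)
#' }
#' @export
synth_dataset <- function(truth, pCa_grid = default_pca_grid(), n_preps = 8,
                          force_sem_scale = 0.05, ktr_sem_scale = 0.10,
                          seed = 1, delta_slack = 1e-8, true_curves = NULL) {
  stopifnot(n_preps >= 2, force_sem_scale >= 0, ktr_sem_scale >= 0)
  if (is.null(true_curves)) {
    force <- force_pca_curve(truth, pCa_grid)$rel_force
    ktr <- vapply(pCa_grid, function(pc)
      ktr_protocol(truth, pc, delta_slack = delta_slack)$ktr, numeric(1))
    true_curves <- list(force = force, ktr = ktr)
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  n_clipped <- 0L
  draw <- function(true, scale) {
    t(vapply(true, function(mu) {
      reps <- rnorm(n_preps, mean = mu, sd = scale * mu)
      n_clipped <<- n_clipped + sum(reps < 0)
      reps <- pmax(reps, 0)
      c(mean(reps), sd(reps) / sqrt(n_preps))
    }, numeric(2)))
  }
  f <- if (force_sem_scale > 0) draw(true_curves$force, force_sem_scale)
       else cbind(true_curves$force, 0)
  k <- if (ktr_sem_scale > 0) draw(true_curves$ktr, ktr_sem_scale)
       else cbind(true_curves$ktr, 0)

  out <- data.frame(pCa = pCa_grid,
                    force_mean = f[, 1], force_sem = f[, 2],
                    ktr_mean = k[, 1], ktr_sem = k[, 2],
                    n = as.integer(n_preps))
  attr(out, "truth") <- truth
  attr(out, "true_curves") <- true_curves
  attr(out, "seed") <- seed
  attr(out, "n_clipped") <- n_clipped
  out
}

check_contractility <- function(d) {
  need <- c("pCa", "force_mean", "force_sem", "ktr_mean", "ktr_sem", "n")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stop("contractility data needs columns ", paste(need, collapse = ", "))
  if (!nrow(d)) stop("contractility data is empty")
  if (any(d$force_sem < 0) || any(d$ktr_sem < 0)) stop("SEMs must be >= 0")
  d[order(-d$pCa), , drop = FALSE]
}

#' Read / write contractility tables
#'
#' CSV tables with header `pCa, force_mean, force_sem, ktr_mean, ktr_sem, n`
#' (relative force P/P0, ktr in 1/s, n preparations per point).
#'
#' @param path file path.
#' @param data a contractility data frame.
#' @return `read_contractility()` returns the validated data frame, sorted
#'   by decreasing pCa; `write_contractility()` returns `path` invisibly.
#' @export
read_contractility <- function(path) {
  check_contractility(read.csv(path))
}

#' @rdname read_contractility
#' @export
write_contractility <- function(data, path) {
  d <- check_contractility(data)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
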