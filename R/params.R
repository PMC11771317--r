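## Model parameters, regime templates and shipped fixtures.

PARAM_NAMES <- c("kBC0", "kBC_Ca2", "kCB0", "kCB_Ca2", "fCM1_0", "fM1C_0",
                 "kM1M2", "kM2M1", "kM2C", "pCa50",
                 "u1", "u2", "z1", "z2", "v", "w",
                 "alpha", "alpha_bar", "beta", "beta_bar")
RATE_NAMES   <- PARAM_NAMES[1:9]
COOP_NAMES   <- c("u1", "u2", "z1", "z2", "v", "w")
FACTOR_NAMES <- c("alpha", "alpha_bar", "beta", "beta_bar")

#' Construct a full model parameter set
#'
#' Bundles the 20 model parameters: 9 reference rate coefficients (1/s), the
#' calcium sensitivity `pCa50`, 6 dimensionless cooperative coefficients
#' (`u1`, `u2` for the blocked-closed RU-RU interaction, `z1`, `z2` for the
#' closed-open RU-RU interaction, `v` for XB-XB, `w` for XB-RU) and 4
#' nearest-neighbor interaction factors in \[0, 1\] (`alpha`/`alpha_bar` mix
#' RU-RU against XB-RU contributions on the blocked-closed step,
#' `beta`/`beta_bar` mix RU-RU against XB-XB on the closed-open step).
#'
#' @param ... named numeric parameters; all 20 of
#'   `c("kBC0","kBC_Ca2","kCB0","kCB_Ca2","fCM1_0","fM1C_0","kM1M2","kM2M1",
#'   "kM2C","pCa50","u1","u2","z1","z2","v","w","alpha","alpha_bar","beta",
#'   "beta_bar")` must be supplied, either individually or as a single named
#'   list / vector.
#' @param allow_anticooperative if `TRUE`, cooperative coefficients in (0, 1)
#'   (anti-cooperative) are accepted with a warning; intended for sensitivity
#'   sweeps only.
#' @return an object of class `tf_params` (a named list of 20 numerics).
#' @examples
#' p <- fixture_params("murine", 2)
#' p$u2
#' @export
tf_params <- function(..., allow_anticooperative = FALSE) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.list(dots[[1]]) || is.numeric(dots[[1]]))) {
    dots <- as.list(dots[[1]])
  }
  missing <- setdiff(PARAM_NAMES, names(dots))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(dots), PARAM_NAMES)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  p <- lapply(dots[PARAM_NAMES], as.numeric)
  class(p) <- "tf_params"
  validate_params(p, allow_anticooperative = allow_anticooperative)
  p
}

validate_params <- function(p, allow_anticooperative = FALSE) {
  vals <- unlist(p[PARAM_NAMES])
  if (any(!is.finite(vals)))
    stop("all parameters must be finite")
  if (any(vals[RATE_NAMES] < 0))
    stop("rate coefficients must be >= 0")
  fac <- vals[FACTOR_NAMES]
  if (any(fac < 0 | fac > 1))
    stop("interaction factors must lie in [0, 1]")
  coop <- vals[COOP_NAMES]
  if (any(coop <= 0))
    stop("cooperative coefficients must be > 0")
  if (any(coop < 1)) {
    if (!allow_anticooperative)
      stop("cooperative coefficients < 1 are anti-cooperative; ",
           "set allow_anticooperative = TRUE to permit them in sweeps")
    warning("cooperative coefficient(s) < 1: anti-cooperative regime")
  }
  invisible(p)
}

#' @export
print.tf_params <- function(x, ...) {
  cat("Thin-filament model parameters\n")
  cat("  rates (1/s): ",
      paste(sprintf("%s=%.4g", RATE_NAMES, unlist(x[RATE_NAMES])),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  pCa50: %.4g\n", x$pCa50))
  cat("  cooperative: ",
      paste(sprintf("%s=%.4g", COOP_NAMES, unlist(x[COOP_NAMES])),
            collapse = ", "), "\n", sep = "")
  cat("  interaction factors: ",
      paste(sprintf("%s=%.4g", FACTOR_NAMES, unlist(x[FACTOR_NAMES])),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write model parameters as JSON
#'
#' Parameters are stored flat, one key per parameter, using the canonical
#' names (see [tf_params()]), so files round-trip exactly.
#'
#' @param path file path.
#' @param params a `tf_params` object.
#' @return `read_params()` returns a `tf_params`; `write_params()` returns
#'   `path` invisibly.
#' @export
read_params <- function(path) {
  tf_params(jsonlite::read_json(path, simplifyVector = TRUE),
            allow_anticooperative = TRUE)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "tf_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## --- regime templates -----------------------------------------------------

SET_SPECS <- list(
  list(set_id = 1L,
       description = "no near-neighbor cooperative interactions",
       fixed = c(u1 = 1, u2 = 1, z1 = 1, z2 = 1, v = 1, w = 1),
       free_factors = FACTOR_NAMES),
  list(set_id = 2L,
       description = "unitary RU-RU interaction",
       fixed = c(v = 1, w = 1, alpha = 1, alpha_bar = 1, beta = 1, beta_bar = 1),
       free_coop = c("u1", "u2", "z1", "z2")),
  list(set_id = 3L,
       description = "unitary XB-XB interaction",
       fixed = c(u1 = 1, u2 = 1, z1 = 1, z2 = 1, w = 1, beta = 0, beta_bar = 0),
       free_coop = "v", free_factors = c("alpha", "alpha_bar")),
  list(set_id = 4L,
       description = "unitary XB-RU interaction",
       fixed = c(u1 = 1, u2 = 1, z1 = 1, z2 = 1, v = 1, alpha = 0, alpha_bar = 0),
       free_coop = "w", free_factors = c("beta", "beta_bar")),
  list(set_id = 5L,
       description = "tandem RU-RU and XB-XB interactions",
       fixed = c(w = 1, alpha = 1, alpha_bar = 1),
       free_coop = c("u1", "u2", "z1", "z2", "v"),
       free_factors = c("beta", "beta_bar")),
  list(set_id = 6L,
       description = "tandem XB-XB and XB-RU interactions",
       fixed = c(u1 = 1, u2 = 1, z1 = 1, z2 = 1,
                 alpha = 0, alpha_bar = 0, beta = 0, beta_bar = 0),
       free_coop = c("v", "w")),
  list(set_id = 7L,
       description = "tandem RU-RU and XB-RU interactions",
       fixed = c(v = 1, beta = 1, beta_bar = 1),
       free_coop = c("u1", "u2", "z1", "z2", "w"),
       free_factors = c("alpha", "alpha_bar")),
  list(set_id = 8L,
       description = "ensemble RU-RU, XB-XB and XB-RU interactions",
       free_coop = COOP_NAMES, free_factors = FACTOR_NAMES)
)

#' Regime template for one of the eight parameter sets
#'
#' Each template states which cooperative coefficients and interaction factors
#' are fixed (at 1 or 0) and which are estimated, with bounds. Set 1 disables
#' all cooperativity; sets 2-4 isolate the unitary RU-RU, XB-XB and XB-RU
#' interactions; sets 5-7 pair them; set 8 frees all ten.
#'
#' @param set_id integer 1 to 8.
#' @param coop_upper upper bound used for free cooperative coefficients
#'   (lower bound 1); interaction-factor bounds are always \[0, 1\].
#' @return an object of class `tf_set_spec`: a list with `set_id`,
#'   `description`, `fixed` (named values) and `free` (named 2-column bound
#'   matrix).
#' @export
param_set_spec <- function(set_id, coop_upper = 50) {
  if (!is.numeric(set_id) || length(set_id) != 1L || !(set_id %in% 1:8))
    stop("set_id must be an integer in 1..8")
  tmpl <- SET_SPECS[[as.integer(set_id)]]
  fixed <- if (is.null(tmpl$fixed)) numeric(0) else tmpl$fixed
  free_names <- c(tmpl$free_coop, tmpl$free_factors)
  free <- matrix(NA_real_, nrow = length(free_names), ncol = 2,
                 dimnames = list(free_names, c("lower", "upper")))
  for (nm in tmpl$free_coop)    free[nm, ] <- c(1, coop_upper)
  for (nm in tmpl$free_factors) free[nm, ] <- c(0, 1)
  spec <- list(set_id = as.integer(set_id), description = tmpl$description,
               fixed = fixed, free = free)
  class(spec) <- "tf_set_spec"
  spec
}

#' @export
print.tf_set_spec <- function(x, ...) {
  cat(sprintf("Parameter set %d: %s\n", x$set_id, x$description))
  if (length(x$fixed))
    cat("  fixed: ", paste(sprintf("%s=%g", names(x$fixed), x$fixed),
                           collapse = ", "), "\n", sep = "")
  if (nrow(x$free))
    cat("  free:  ", paste(sprintf("%s in [%g, %g]", rownames(x$free),
                                   x$free[, 1], x$free[, 2]),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Impose a regime template on a parameter set
#'
#' Overwrites the coefficients fixed by `spec` with their template values,
#' leaving all other parameters untouched.
#'
#' @param params a `tf_params`.
#' @param spec a `tf_set_spec` from [param_set_spec()].
#' @return a `tf_params`.
#' @export
apply_set_spec <- function(params, spec) {
  stopifnot(inherits(params, "tf_params"), inherits(spec, "tf_set_spec"))
  p <- unclass(params)
  for (nm in names(spec$fixed)) p[[nm]] <- unname(spec$fixed[[nm]])
  class(p) <- "tf_params"
  validate_params(p)
}

## check that a parameter set satisfies a regime template
conforms_to_spec <- function(params, spec, tol = 0) {
  all(vapply(names(spec$fixed), function(nm)
    abs(params[[nm]] - spec$fixed[[nm]]) <= tol, logical(1)))
}

#' Published fitted parameter columns
#'
#' Returns the fitted parameter column for one species and regime, as shipped
#' with the package (sets 1, 2 and 8 for murine and porcine ventricular
#' myocardium; fitted values for sets 3-7 were not published).
#'
#' @param species `"murine"` or `"porcine"`.
#' @param set_id 1, 2 or 8.
#' @return a `tf_params`.
#' @examples
#' fixture_params("porcine", 8)$u2
#' @export
fixture_params <- function(species = c("murine", "porcine"), set_id) {
  species <- match.arg(species)
  file <- system.file("extdata", sprintf("%s_set%d.json", species, set_id),
                      package = "thinfil")
  if (file == "")
    stop("no shipped fitted parameters for ", species, " set ", set_id,
         " (only sets 1, 2 and 8 were published)")
  read_params(file)
}

#' Shipped sensitivity-sweep configurations
#'
#' Sweep configurations for the RU-RU cooperative coefficients `u2` and `z2`
#' around the species' ensemble (set 8) fit, probed at pCa 6.1 and 4.5.
#'
#' @param species `"murine"` or `"porcine"`.
#' @param coefficient `"u2"` or `"z2"`.
#' @return a list with `species`, `vary`, `values` and `pCa`.
#' @export
sweep_config <- function(species = c("murine", "porcine"),
                         coefficient = c("u2", "z2")) {
  species <- match.arg(species)
  coefficient <- match.arg(coefficient)
  file <- system.file("extdata",
                      sprintf("%s_%s_sweep.json", species, coefficient),
                      package = "thinfil")
  jsonlite::read_json(file, simplifyVector = TRUE)
}
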