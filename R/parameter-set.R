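#' Global parameter set for fitting
#'
#' Bundles the per-step Arrhenius parameters of one mechanism with the
#' baseline (extinction) parameters shared across all traces. Rate constants
#' are handled in log10 space by the optimiser; activation energies and
#' baseline coefficients in linear space.
#'
#' @param steps list of [rate_params()], one per step of the mechanism
#'   (3 for model1, 4 for model2; step 4 is the D = Dstar trap)
#' @param baseline numeric length 4: `eps_M_intercept`, `eps_M_slope`,
#'   `eps_T_intercept`, `eps_T_slope` (AU cm^-1 M^-1 strand; per degC)
#' @param dialect extinction dialect, see [extinction_model()]
#' @param T_ref shared reference temperature, K (fixed metadata, not fitted)
#' @return object of class `parameter_set`
#' @export
parameter_set <- function(steps, baseline, dialect = "midpoint",
                          T_ref = 298.15) {
  stopifnot(length(baseline) == 4, all(vapply(steps, inherits, TRUE,
                                              "rate_params")))
  names(baseline) <- c("eps_M_intercept", "eps_M_slope",
                       "eps_T_intercept", "eps_T_slope")
  structure(list(steps = steps, baseline = baseline, dialect = dialect,
                 T_ref = T_ref),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set: %d steps, dialect '%s'>\n",
              length(x$steps), x$dialect))
  for (i in seq_along(x$steps)) { cat(sprintf(" step %d: ", i)); print(x$steps[[i]]) }
  cat(" baseline:", paste(sprintf("%s=%.4g", names(x$baseline), x$baseline),
                          collapse = ", "), "\n")
  invisible(x)
}

# ---- flat-vector packing used by the optimiser ---------------------------

.pvec_names <- function(n_steps) {
  c(as.vector(vapply(seq_len(n_steps), function(i)
      paste0(c("log10_kf", "Ea_f", "log10_kr", "Ea_r"), "_", i),
      character(4))),
    "eps_M_intercept", "eps_M_slope", "eps_T_intercept", "eps_T_slope")
}

.pack_params <- function(pset) {
  v <- unlist(lapply(pset$steps, function(p)
    c(log10(p$k_f_ref), p$Ea_f, log10(p$k_r_ref), p$Ea_r)))
  v <- c(v, pset$baseline)
  names(v) <- .pvec_names(length(pset$steps))
  v
}

.unpack_params <- function(pvec, n_steps, dialect = "midpoint",
                           T_ref = 298.15) {
  steps <- lapply(seq_len(n_steps), function(i) {
    j <- 4 * (i - 1)
    rate_params(10^pvec[[j + 1]], pvec[[j + 2]], 10^pvec[[j + 3]],
                pvec[[j + 4]], T_ref = T_ref)
  })
  parameter_set(steps, baseline = unname(pvec[4 * n_steps + 1:4]),
                dialect = dialect, T_ref = T_ref)
}

#' Default optimiser bounds for a mechanism
#'
#' log10 rate constants are bounded generously; activation energies are
#' bounded to 0..100 kcal/mol; baselines to a broad physically plausible
#' window around typical 265 nm oligonucleotide coefficients.
#'
#' @param model_name `"model1"` or `"model2"`
#' @return list with `lower` and `upper` named vectors
#' @export
default_bounds <- function(model_name = c("model1", "model2")) {
  model_name <- match.arg(model_name)
  n_steps <- if (model_name == "model1") 3L else 4L
  lo_step <- c(-6, 0, -12, 0)
  hi_step <- c(8, 100, 6, 100)
  lower <- c(rep(lo_step, n_steps), 1e3, -200, 1e3, -200)
  upper <- c(rep(hi_step, n_steps), 2e5, 500, 2e5, 500)
  names(lower) <- names(upper) <- .pvec_names(n_steps)
  list(lower = lower, upper = upper)
}

# extinction model for one trace's path length from the shared baselines
.ext_from_pset <- function(pset, path_length) {
  extinction_model(pset$baseline[1], pset$baseline[2],
                   pset$baseline[3], pset$baseline[4],
                   dialect = pset$dialect, path_length = path_length)
}

# assembly model carrying the pset's kinetic parameters
.model_from_pset <- function(model_name, pset) {
  n_need <- if (model_name == "model1") 3L else 4L
  stopifnot(length(pset$steps) == n_need)
  build_model(model_name, pset$steps)
}
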