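#' Extinction-coefficient model at 265 nm
#'
#' Folded i-motif states are hypochromic at 265 nm, so the per-strand
#' coefficient of the tetramer lies below that of the free strand at every
#' temperature in range. Both endpoint coefficients are linear in temperature
#' (the sloping pre- and post-transition baselines of a UV melting trace);
#' the intermediate species carry no slope parameters of their own but are
#' derived from the endpoints according to a `dialect`:
#'
#' * `"midpoint"`: the dimer (and the trap, spectrally indistinguishable from
#'   it) absorbs half-way between monomer and tetramer per strand,
#'   `eps_D = (eps_M + eps_T4)/2`, and the trimer one quarter of the way up,
#'   `eps_Tri = (eps_M + 3 eps_T4)/4`.
#' * `"tetramer_fraction"`: per complex, the dimer absorbs half and the trimer
#'   three quarters of the tetramer complex; per strand both then equal
#'   `eps_T4`.
#'
#' @param eps_M_intercept,eps_M_slope monomer (unfolded strand) coefficient:
#'   value at 0 degC (AU cm^-1 M^-1 strand) and slope per degC
#' @param eps_T_intercept,eps_T_slope per-strand tetramer coefficient,
#'   same units
#' @param dialect how intermediate-species coefficients derive from the
#'   endpoints (see Details); if left missing, `"midpoint"` is used and a
#'   message records that the convention was defaulted
#' @param path_length optical path, cm
#' @param T_range temperatures (degC) over which the invariants are checked
#' @return object of class `extinction_model`
#' @export
extinction_model <- function(eps_M_intercept, eps_M_slope = 0,
                             eps_T_intercept, eps_T_slope = 0,
                             dialect = c("midpoint", "tetramer_fraction"),
                             path_length = 0.1, T_range = c(-5, 95)) {
  if (missing(dialect))
    message("extinction dialect not set; defaulting to 'midpoint' ",
            "(dimer half-way between monomer and tetramer)")
  dialect <- match.arg(dialect)
  stopifnot(path_length > 0)
  Tchk <- seq(T_range[1], T_range[2], by = 1)
  eM <- eps_M_intercept + eps_M_slope * Tchk
  eT <- eps_T_intercept + eps_T_slope * Tchk
  if (any(eM <= 0) || any(eT <= 0))
    stop("extinction coefficients must stay positive over ",
         T_range[1], "..", T_range[2], " degC")
  if (any(eM < eT))
    stop("hypochromicity violated: monomer coefficient must be >= tetramer ",
         "coefficient at every temperature in range")
  structure(list(eps_M_intercept = eps_M_intercept, eps_M_slope = eps_M_slope,
                 eps_T_intercept = eps_T_intercept, eps_T_slope = eps_T_slope,
                 dialect = dialect, path_length = path_length),
            class = "extinction_model")
}

# per-strand extinction coefficients of every species at temperatures T_C;
# returns a matrix |T| x 5 with columns names(STRANDS)
.eps_per_strand <- function(ext, T_C) {
  eM <- ext$eps_M_intercept + ext$eps_M_slope * T_C
  eT <- ext$eps_T_intercept + ext$eps_T_slope * T_C
  if (ext$dialect == "midpoint") {
    eD <- (eM + eT) / 2
    eTri <- (eM + 3 * eT) / 4
  } else if (ext$dialect == "tetramer_fraction") {
    # per complex: eps(D-complex) = 0.5 * eps(T-complex) = 0.5 * 4 eT -> /2
    # strands; eps(Tri-complex) = 0.75 * 4 eT -> /3 strands
    eD <- 0.5 * 4 * eT / 2
    eTri <- 0.75 * 4 * eT / 3
  } else stop("unknown extinction dialect: ", ext$dialect)
  cbind(M = eM, D = eD, Dstar = eD, Tri = eTri, T = eT)
}

#' Absorbance of a species state
#'
#' Beer-Lambert over all species:
#' \eqn{A = l \sum_i \epsilon_i(T)\, n_i [S_i]} with per-strand coefficients
#' \eqn{\epsilon_i}, strand counts \eqn{n_i} and complex molarities
#' \eqn{[S_i]}.
#'
#' @param state a [species_state()], or a matrix with one row per time point
#'   and columns `M, D, Dstar, Tri, T`
#' @param T_C temperature(s), degC (scalar or one per row)
#' @param ext an [extinction_model()]
#' @return absorbance in AU (vector if `state` is a matrix)
#' @export
absorbance <- function(state, T_C, ext) {
  if (is.matrix(state)) x <- state[, names(STRANDS), drop = FALSE]
  else x <- matrix(as.numeric(state[names(STRANDS)]), nrow = 1,
                   dimnames = list(NULL, names(STRANDS)))
  eps <- .eps_per_strand(ext, T_C)
  strands <- matrix(STRANDS, nrow(x), 5, byrow = TRUE)
  ext$path_length * rowSums(eps * strands * x)
}
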