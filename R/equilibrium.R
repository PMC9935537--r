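#' Thermodynamic equilibrium state at a fixed temperature
#'
#' Solves the coupled mass-action equilibria under the strand-mass
#' constraint. With stepwise association constants \eqn{K_1 = [D]/[M]^2},
#' \eqn{K_2 = [Tri]/([D][M])}, \eqn{K_3 = [T]/([Tri][M])} and (model2)
#' \eqn{K_{trap} = [D^*]/[D]}, the free-monomer concentration m solves
#' \deqn{m + 2K_1(1+K_{trap})m^2 + 3K_1K_2 m^3 + 4K_1K_2K_3 m^4 = C_{tot},}
#' a strictly increasing quartic with a unique physical root, found by
#' bisection and polished by Newton to near machine precision.
#'
#' @param model an [build_model()] network; every step must be reversible
#'   (`k_r_ref > 0`) unless its forward rate is also zero (inert step)
#' @param T_K absolute temperature, K
#' @param C_tot total strand concentration, mol/L
#' @return a [species_state()]
#' @export
equilibrium_state <- function(model, T_K, C_tot) {
  stopifnot(C_tot > 0, T_K > 0)
  K <- vapply(model$steps, function(s) {
    kf <- arrhenius_rate(s$params, "forward", T_K)
    kr <- arrhenius_rate(s$params, "reverse", T_K)
    if (kr == 0) {
      if (kf == 0) return(0) # inert step contributes no bound species
      stop("irreversible step (k_r = 0 with k_f > 0): no finite equilibrium")
    }
    kf / kr
  }, numeric(1))
  K1 <- K[1]
  K2 <- if (length(K) >= 2) K[2] else 0
  K3 <- if (length(K) >= 3) K[3] else 0
  Ktrap <- if (model$name == "model2") K[4] else 0

  total <- function(m)
    m + 2 * K1 * (1 + Ktrap) * m^2 + 3 * K1 * K2 * m^3 +
      4 * K1 * K2 * K3 * m^4
  dtotal <- function(m)
    1 + 4 * K1 * (1 + Ktrap) * m + 9 * K1 * K2 * m^2 +
      16 * K1 * K2 * K3 * m^3

  # bracket then bisect: total() is strictly increasing on [0, C_tot]
  lo <- 0; hi <- C_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (total(mid) < C_tot) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-9 * C_tot) break
  }
  m <- (lo + hi) / 2
  for (i in 1:6) m <- m - (total(m) - C_tot) / dtotal(m) # Newton polish
  m <- max(m, 0)

  D <- K1 * m^2
  species_state(M = m, D = D, Dstar = Ktrap * D, Tri = K2 * D * m,
                T = K3 * K2 * D * m^2)
}

#' Equilibrium absorbance curve over a temperature span
#'
#' The infinitely-slow-scan reference against which hysteresis is measured.
#'
#' @param model,C_tot,ext as [simulate_program()]
#' @param T_span span `c(low, high)`, degC
#' @param grid_C spacing, degC
#' @return a `th_trace` (with `time_s = NA`, `direction = "equilibrium"`)
#' @export
equilibrium_curve <- function(model, C_tot, ext, T_span = c(5, 85),
                              grid_C = 0.25) {
  T_C <- seq(min(T_span), max(T_span), by = grid_C)
  states <- t(vapply(T_C, function(tc)
    as.numeric(equilibrium_state(model, celsius_to_kelvin(tc), C_tot)),
    numeric(5)))
  colnames(states) <- names(STRANDS)
  A <- absorbance(states, T_C, ext)
  .new_trace(rep(NA_real_, length(T_C)), T_C, A, states,
             conditions = list(C_tot = C_tot, direction = "equilibrium",
                               rate = 0, path_length = ext$path_length))
}

# net flux through every step at a state (M/s); ~0 at equilibrium
.step_fluxes <- function(model, state, T_K) {
  x <- as.numeric(state[names(STRANDS)])
  names(x) <- names(STRANDS)
  vapply(model$steps, function(s) {
    kf <- arrhenius_rate(s$params, "forward", T_K)
    kr <- arrhenius_rate(s$params, "reverse", T_K)
    kf * prod(x[s$reactants]) - kr * x[[s$products]]
  }, numeric(1))
}
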