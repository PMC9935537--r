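#' Arrhenius rate parameters for one reversible elementary step
#'
#' Both directions of a step are parameterised by a rate constant at a
#' reference temperature and an activation energy, so that
#' \deqn{k(T) = k_\mathrm{ref} \exp\{-(E_a/R)(1/T - 1/T_\mathrm{ref})\}.}
#' The step enthalpy follows as \eqn{\Delta H^\circ = E_{a,f} - E_{a,r}}
#' (kcal/mol) and the equilibrium constant as \eqn{K(T) = k_f(T)/k_r(T)}.
#'
#' @param k_f_ref forward rate constant at `T_ref` (M^-1 s^-1 for a
#'   bimolecular step, s^-1 for a unimolecular one)
#' @param Ea_f forward activation energy, kcal/mol
#' @param k_r_ref reverse rate constant at `T_ref`, s^-1 (the reverse of every
#'   supported step is unimolecular)
#' @param Ea_r reverse activation energy, kcal/mol
#' @param T_ref reference temperature, K
#' @return an object of class `rate_params`
#' @examples
#' rp <- rate_params(k_f_ref = 1e3, Ea_f = 20, k_r_ref = 1e-2, Ea_r = 55)
#' arrhenius_rate(rp, "forward", 308.15)
#' @export
rate_params <- function(k_f_ref, Ea_f, k_r_ref, Ea_r, T_ref = 298.15) {
  stopifnot(is.numeric(k_f_ref), is.numeric(k_r_ref),
            length(k_f_ref) == 1L, length(k_r_ref) == 1L)
  if (k_f_ref < 0 || k_r_ref < 0)
    stop("rate constants must be nonnegative")
  if (T_ref <= 0) stop("T_ref must be positive (Kelvin)")
  structure(list(k_f_ref = k_f_ref, Ea_f = Ea_f,
                 k_r_ref = k_r_ref, Ea_r = Ea_r, T_ref = T_ref),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat(sprintf("k_f(%g K) = %.4g, Ea_f = %g kcal/mol; k_r = %.4g, Ea_r = %g (dH = %g)\n",
              x$T_ref, x$k_f_ref, x$Ea_f, x$k_r_ref, x$Ea_r, x$Ea_f - x$Ea_r))
  invisible(x)
}

#' Evaluate an Arrhenius rate constant
#'
#' @param params a [rate_params()] object
#' @param direction `"forward"` or `"reverse"`
#' @param T_K absolute temperature, K (vectorised)
#' @return rate constant(s) at `T_K`, same units as the reference constant
#' @export
arrhenius_rate <- function(params, direction = c("forward", "reverse"), T_K) {
  direction <- match.arg(direction)
  if (any(!is.finite(T_K)) || any(T_K <= 0))
    stop("temperature must be positive (Kelvin)")
  if (direction == "forward") {
    k_ref <- params$k_f_ref; Ea <- params$Ea_f
  } else {
    k_ref <- params$k_r_ref; Ea <- params$Ea_r
  }
  k_ref * exp(-(Ea / RGAS) * (1 / T_K - 1 / params$T_ref))
}

#' Species populations at one time point
#'
#' Concentrations are complex molarity (mol/L of each oligomeric complex);
#' [strand_total()] converts to the strand molarity that matches the total
#' oligonucleotide concentration of an experiment.
#'
#' @param M,D,Dstar,Tri,T complex molarities; `Dstar` is only meaningful for
#'   the trap-containing mechanism but is always carried (zero otherwise)
#' @return object of class `species_state` (named numeric vector)
#' @export
species_state <- function(M = 0, D = 0, Dstar = 0, Tri = 0, T = 0) {
  x <- c(M = M, D = D, Dstar = Dstar, Tri = Tri, T = T)
  if (any(!is.finite(x)) || any(x < 0))
    stop("species concentrations must be finite and nonnegative")
  structure(x, class = "species_state")
}

#' Total strand molarity of a state
#'
#' An n-mer complex at concentration c contributes n*c strands:
#' `[M] + 2[D] + 2[Dstar] + 3[Tri] + 4[T]`.
#'
#' @param state a [species_state()] (or plain named vector of the same layout)
#' @return strand molarity, mol/L
#' @export
strand_total <- function(state) {
  sum(STRANDS[names(STRANDS)] * as.numeric(state[names(STRANDS)]))
}

#' A reversible elementary assembly step
#'
#' @param reactants character vector of species labels (length 2 for a
#'   bimolecular association, length 1 for an isomerisation)
#' @param products single product species label
#' @param params a [rate_params()] object
#' @return object of class `reaction_step`
#' @export
reaction_step <- function(reactants, products, params) {
  stopifnot(all(reactants %in% names(STRANDS)),
            all(products %in% names(STRANDS)),
            length(products) == 1L, length(reactants) %in% 1:2,
            inherits(params, "rate_params"))
  if (sum(STRANDS[reactants]) != sum(STRANDS[products]))
    stop("strand count not conserved by step ",
         paste(reactants, collapse = "+"), " -> ", products)
  structure(list(reactants = reactants, products = products,
                 molecularity_f = length(reactants), params = params),
            class = "reaction_step")
}

# the step topology of each mechanism (label pairs -> product)
.model_steps <- function(name) {
  base <- list(list(c("M", "M"), "D"),
               list(c("D", "M"), "Tri"),
               list(c("Tri", "M"), "T"))
  if (name == "model2") base <- c(base, list(list("D", "Dstar")))
  base
}

.model_species <- function(name) {
  if (name == "model1") c("M", "D", "Tri", "T") else c("M", "D", "Dstar", "Tri", "T")
}

# neutral placeholder kinetics used when build_model() is called without
# parameters; deliberately inert (all rates zero) so nothing is implied
.null_params <- function() rate_params(0, 0, 0, 0)

#' Build one of the two supported assembly mechanisms
#'
#' `model1` is the strictly sequential tetramer assembly
#' M+M = D, D+M = Tri, Tri+M = T. `model2` adds the off-pathway dimeric trap
#' as a unimolecular isomerisation of the on-pathway dimer, D = Dstar, so
#' that `model1` is nested in `model2` (silencing the trap step reproduces
#' `model1` exactly).
#'
#' @param name `"model1"` or `"model2"`
#' @param params optional list of [rate_params()], one per step in the order
#'   above; defaults to inert (all-zero) rates that must be replaced before
#'   simulating
#' @return object of class `assembly_model`
#' @examples
#' m <- build_model("model2", default_truth("model2")$steps)
#' m$species
#' @export
build_model <- function(name = c("model1", "model2"), params = NULL) {
  name <- match.arg(name)
  topo <- .model_steps(name)
  if (is.null(params)) params <- replicate(length(topo), .null_params(),
                                           simplify = FALSE)
  if (length(params) != length(topo))
    stop(name, " needs exactly ", length(topo), " parameter sets")
  steps <- Map(function(tp, pp) reaction_step(tp[[1]], tp[[2]], pp),
               topo, params)
  structure(list(name = name, species = .model_species(name), steps = steps),
            class = "assembly_model")
}

#' @export
print.assembly_model <- function(x, ...) {
  cat(sprintf("<assembly_model %s: %d species, %d steps>\n",
              x$name, length(x$species), length(x$steps)))
  for (s in x$steps)
    cat(" ", paste(s$reactants, collapse = " + "), "<=>", s$products, "\n")
  invisible(x)
}

#' Mass-action time derivatives of all species
#'
#' Pure-R reference implementation of the rate law used by the compiled
#' integrator: for a bimolecular step A+B->C the event rate is
#' `k_f [A][B] - k_r [C]`, and each reactant slot contributes -v (so M+M->D
#' gives dM/dt = -2 k_f \[M\]^2, dD/dt = +k_f \[M\]^2). Strand mass is
#' conserved analytically: `sum(strands * deriv) == 0`.
#'
#' @param model an [build_model()] network
#' @param state a [species_state()]
#' @param T_K absolute temperature, K
#' @return named numeric vector of d\[S\]/dt, M/s, over `names(STRANDS)`
#' @export
rate_of_change <- function(model, state, T_K) {
  x <- as.numeric(state[names(STRANDS)])
  names(x) <- names(STRANDS)
  if (any(x < 0)) stop("negative concentrations")
  dx <- setNames(numeric(length(x)), names(x))
  for (s in model$steps) {
    kf <- arrhenius_rate(s$params, "forward", T_K)
    kr <- arrhenius_rate(s$params, "reverse", T_K)
    v <- kf * prod(x[s$reactants]) - kr * x[[s$products]]
    for (r in s$reactants) dx[[r]] <- dx[[r]] - v
    dx[[s$products]] <- dx[[s$products]] + v
  }
  dx
}

# --- model JSON round trip ------------------------------------------------

#' Export / import an assembly model as JSON
#'
#' Species, steps and rate parameters are written with explicit units so a
#' model file is self-describing.
#'
#' @param model an `assembly_model`
#' @param path file path; for `model_from_json` a path or JSON string
#' @return `model_to_json` returns `path` invisibly; `model_from_json`
#'   returns the reconstructed `assembly_model`
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    name = model$name,
    species = model$species,
    units = list(concentration = "mol/L (complex)", temperature = "K",
                 energy = "kcal/mol", bimolecular_rate = "M^-1 s^-1",
                 unimolecular_rate = "s^-1"),
    steps = lapply(model$steps, function(s)
      list(reactants = as.list(s$reactants), products = s$products,
           params = unclass(s$params))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- lapply(obj$steps, function(s) do.call(rate_params, s$params))
  m <- build_model(obj$name, params)
  stopifnot(identical(m$species, unlist(obj$species)))
  m
}
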