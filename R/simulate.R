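#' Simulate an absorbance trace along a temperature program
#'
#' Integrates the mass-action network with a stiff-capable adaptive
#' Rosenbrock method while the temperature follows `program`, then converts
#' species populations to absorbance. Species trajectories stay nonnegative
#' and strand mass is conserved to better than 1e-6 relative (the scheme
#' preserves linear invariants to roundoff).
#'
#' @param model an [build_model()] network with nonzero rate parameters
#' @param program a [temperature_program()]
#' @param C_tot total strand concentration, mol/L (strand molarity)
#' @param init initial populations: `"equilibrium"` (thermodynamic equilibrium
#'   at the program's starting temperature), `"all_monomer"`, or an explicit
#'   [species_state()] whose strand total must match `C_tot` to 1e-6 relative
#' @param ext an [extinction_model()]
#' @param grid_C output spacing along ramps, degC (default 0.25, an
#'   instrument-style sampling)
#' @param rtol,atol integrator tolerances (relative; absolute, mol/L)
#' @param keep_species keep per-point species molarities in the trace?
#' @param method integration scheme: `"rodas3"` (L-stable 3rd order, default)
#'   or `"kr4"` (Kaps-Rentrop 4th order, for high-accuracy reference runs)
#' @return a `th_trace`: data frame columns `time_s`, `temperature_C`,
#'   `absorbance_AU`, optional species columns, plus a `conditions` attribute
#' @export
simulate_program <- function(model, program, C_tot,
                             init = c("equilibrium", "all_monomer"),
                             ext, grid_C = 0.25, rtol = 1e-7, atol = 1e-11,
                             keep_species = TRUE, method = "rodas3") {
  y0 <- .resolve_init(model, init, C_tot, program$segments[[1]]$T_start)
  out_t <- .program_out_times(program, grid_C)
  conc <- .integrate(model, y0, .program_matrix(program), out_t, rtol, atol,
                     method)
  T_C <- kelvin_to_celsius(conc[, ncol(conc)])
  states <- .full_species(conc, model$species)
  A <- absorbance(states, T_C, ext)
  .new_trace(out_t, T_C, A, states,
             conditions = list(C_tot = C_tot, direction = "program",
                               rate = NA_real_,
                               path_length = ext$path_length),
             keep_species = keep_species)
}

# map integrator output (model-species columns + T) to the full 5-species set
.full_species <- function(conc, species) {
  out <- matrix(0, nrow(conc), 5, dimnames = list(NULL, names(STRANDS)))
  out[, species] <- conc[, seq_along(species), drop = FALSE]
  out
}

.resolve_init <- function(model, init, C_tot, T_start_C) {
  if (is.character(init)) {
    init <- match.arg(init, c("equilibrium", "all_monomer"))
    if (init == "all_monomer") {
      st <- species_state(M = C_tot)
    } else {
      st <- equilibrium_state(model, celsius_to_kelvin(T_start_C), C_tot)
    }
  } else {
    st <- init
    tot <- strand_total(st)
    if (abs(tot - C_tot) > 1e-6 * C_tot)
      stop("initial state strand total (", signif(tot, 6),
           ") does not match C_tot (", signif(C_tot, 6), ")")
  }
  as.numeric(st[model$species])
}

# low-level bridge to the compiled core; raises a diagnostic error carrying
# the last good state on integrator failure
.integrate <- function(model, y0, seg_mat, out_t, rtol, atol,
                       method = c("rodas3", "kr4")) {
  method_i <- match(match.arg(method), c("rodas3", "kr4")) - 1L
  sp <- model$species
  idx <- function(lbl) match(lbl, sp) - 1L
  r1 <- integer(0); r2 <- integer(0); pr <- integer(0)
  par <- matrix(0, length(model$steps), 5)
  for (i in seq_along(model$steps)) {
    s <- model$steps[[i]]
    r1[i] <- idx(s$reactants[1])
    r2[i] <- if (length(s$reactants) == 2L) idx(s$reactants[2]) else -1L
    pr[i] <- idx(s$products)
    p <- s$params
    par[i, ] <- c(p$k_f_ref, p$Ea_f, p$k_r_ref, p$Ea_r, p$T_ref)
  }
  res <- .sim_network(y0, r1, r2, pr, par, seg_mat, out_t, rtol, atol,
                      method_i)
  if (!res$ok) {
    cond <- structure(class = c("imotifTH_integrator_error", "error",
                                "condition"),
                      list(message = paste0("integrator failure: ",
                                            res$errmsg),
                           call = sys.call(-1),
                           t_last = res$t_last,
                           state_last = res$conc))
    stop(cond)
  }
  res$conc
}

.new_trace <- function(time_s, T_C, A, states, conditions,
                       keep_species = TRUE) {
  df <- data.frame(time_s = time_s, temperature_C = T_C, absorbance_AU = A)
  if (keep_species) df <- cbind(df, as.data.frame(states))
  attr(df, "conditions") <- conditions
  class(df) <- c("th_trace", "data.frame")
  df
}

#' @export
print.th_trace <- function(x, ...) {
  cc <- attr(x, "conditions")
  cat(sprintf("<th_trace: %d points, %.1f..%.1f degC, %s, C_tot = %g uM strand>\n",
              nrow(x), min(x$temperature_C), max(x$temperature_C),
              cc$direction %||% "program", (cc$C_tot %||% NA) * 1e6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a heating or cooling ramp under the standard protocols
#'
#' Mirrors the anneal-then-melt cycle of a TH experiment. A cooling trace
#' starts from thermodynamic equilibrium at the upper temperature
#' (effectively all monomer at 85 degC). A heating trace, by default
#' (`init_protocol = "anneal_same_rate"`), starts from the final state of a
#' simulated cooling ramp at the same rate; alternatives are equilibrium at
#' the starting temperature, all monomer (an instantaneous snap-cool), or an
#' explicit state.
#'
#' @param model,C_tot,ext,grid_C,rtol,atol,keep_species as [simulate_program()]
#' @param direction `"heating"` or `"cooling"`
#' @param rate scan rate, degC/min (> 0)
#' @param T_span temperature span `c(low, high)`, degC
#' @param init_protocol heating-trace initial state:
#'   `"anneal_same_rate"`, `"equilibrium"`, `"all_monomer"`, or a
#'   [species_state()]
#' @return a `th_trace`
#' @export
simulate_ramp <- function(model, direction = c("heating", "cooling"), rate,
                          C_tot, ext, T_span = c(5, 85),
                          init_protocol = "anneal_same_rate", grid_C = 0.25,
                          rtol = 1e-7, atol = 1e-11, keep_species = TRUE,
                          method = "rodas3") {
  direction <- match.arg(direction)
  lo <- min(T_span); hi <- max(T_span)
  if (direction == "cooling") {
    prog <- temperature_program(ramp_segment(hi, lo, rate))
    tr <- simulate_program(model, prog, C_tot, "equilibrium", ext,
                           grid_C, rtol, atol, keep_species, method)
  } else {
    prog <- temperature_program(ramp_segment(lo, hi, rate))
    init <- init_protocol
    if (is.character(init_protocol)) {
      init <- switch(init_protocol,
        anneal_same_rate = {
          cool <- simulate_ramp(model, "cooling", rate, C_tot, ext, T_span,
                                grid_C = grid_C, rtol = rtol, atol = atol,
                                keep_species = TRUE, method = method)
          st <- as.numeric(tail(cool, 1)[, names(STRANDS)])
          names(st) <- names(STRANDS)
          # renormalise the (tiny) integrator drift so init matches C_tot
          st * C_tot / strand_total(st)
        },
        equilibrium = "equilibrium",
        all_monomer = "all_monomer",
        stop("unknown init_protocol: ", init_protocol))
    }
    tr <- simulate_program(model, prog, C_tot, init, ext,
                           grid_C, rtol, atol, keep_species, method)
  }
  attr(tr, "conditions")$direction <- direction
  attr(tr, "conditions")$rate <- rate
  attr(tr, "conditions")$init_protocol <-
    if (is.character(init_protocol)) init_protocol else "explicit"
  tr
}

#' Isothermal population time course
#'
#' Constant-temperature integration reporting strand-normalised species
#' fractions, as used for snap-cool kinetic-trap simulations (e.g. 24 h at
#' 4 degC). Supports long horizons (days to weeks of simulated time); output
#' times are log-spaced by default so both the fast dimerisation and the slow
#' tetramer rise are resolved.
#'
#' @param model,C_tot as [simulate_program()]
#' @param T_C hold temperature, degC
#' @param init `"all_monomer"` (the snap-cool protocol), `"equilibrium"`, or
#'   a [species_state()]
#' @param duration simulated time, s
#' @param n_out number of output points
#' @param log_time log-spaced output times (default) or linear
#' @param rtol,atol integrator tolerances
#' @return data frame: `time_s`, per-species complex molarity columns and
#'   `frac_*` strand-fraction columns
#' @export
isothermal_course <- function(model, T_C, C_tot, init = "all_monomer",
                              duration, n_out = 400, log_time = TRUE,
                              rtol = 1e-7, atol = 1e-11,
                              method = "rodas3") {
  stopifnot(duration > 0)
  y0 <- .resolve_init(model, init, C_tot, T_C)
  tt <- if (log_time)
    c(0, 10^seq(log10(max(duration * 1e-7, 1e-3)), log10(duration),
                length.out = n_out - 1L))
  else seq(0, duration, length.out = n_out)
  seg <- matrix(c(0, duration, celsius_to_kelvin(T_C), 0), 1)
  conc <- .integrate(model, y0, seg, tt, rtol, atol, method)
  states <- .full_species(conc, model$species)
  fr <- sweep(states, 2, STRANDS, `*`) / C_tot
  colnames(fr) <- paste0("frac_", names(STRANDS))
  out <- cbind(data.frame(time_s = tt), as.data.frame(states),
               as.data.frame(fr))
  attr(out, "conditions") <- list(C_tot = C_tot, T_C = T_C)
  out
}
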