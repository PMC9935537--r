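#' Global residual vector of a parameter set against a dataset
#'
#' Concatenated `A_observed - A_simulated` over every trace, each simulated
#' on its own time grid under its own conditions and initial-state protocol
#' (a cooling trace from equilibrium at the upper temperature; a heating
#' trace from the end state of the matching cooling ramp, which is computed
#' once per concentration-rate cell and shared). Within one evaluation the
#' shared kinetic and baseline parameters are common to all traces.
#'
#' If a parameter point makes the simulation fail (integrator collapse,
#' baseline sign violation), the affected trace's residuals are set to a
#' large penalty so optimisers survive; `strict = TRUE` raises instead.
#'
#' @param model_name `"model1"` or `"model2"`
#' @param pset a [parameter_set()] (or packed parameter vector)
#' @param dataset a `th_dataset` (or plain list of `th_trace`)
#' @param rtol,atol integrator tolerances (fitting default trades a little
#'   accuracy for speed; well below the noise floor)
#' @param strict raise on simulation failure instead of penalising
#' @return numeric residual vector, `attr(,"by_trace")` holding the split
#' @export
residuals_global <- function(model_name, pset, dataset, rtol = 1e-7,
                             atol = 1e-11, strict = FALSE) {
  if (!inherits(pset, "parameter_set"))
    pset <- .unpack_params(pset, if (model_name == "model1") 3L else 4L)
  sims <- .simulate_dataset(model_name, pset, dataset, rtol, atol, strict)
  by_trace <- lapply(seq_along(dataset), function(i) {
    obs <- dataset[[i]]$absorbance_AU
    if (is.null(sims[[i]])) rep(1e3, length(obs)) # penalty
    else obs - sims[[i]]
  })
  names(by_trace) <- names(dataset)
  out <- unlist(by_trace, use.names = FALSE)
  attr(out, "by_trace") <- by_trace
  out
}

# simulate model absorbance for every trace of a dataset; returns a list of
# absorbance vectors (NULL where simulation failed and strict = FALSE)
.simulate_dataset <- function(model_name, pset, dataset, rtol, atol,
                              strict = FALSE) {
  model <- try(.model_from_pset(model_name, pset), silent = TRUE)
  exts <- list()
  cool_cache <- new.env(parent = emptyenv())
  lapply(dataset, function(tr) {
    cond <- attr(tr, "conditions")
    res <- try({
      if (inherits(model, "try-error")) stop("invalid kinetic parameters")
      ext <- .ext_from_pset(pset, cond$path_length)
      .trace_prediction(model, pset, tr, ext, cool_cache, rtol, atol)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      if (strict) stop(attr(res, "condition"))
      warning("simulation failed for trace (", cond$direction, ", ",
              cond$C_tot * 1e6, " uM, ", cond$rate,
              " degC/min); penalty residuals used", call. = FALSE)
      NULL
    } else res
  })
}

# absorbance prediction on one trace's own grid, honouring its protocol
.trace_prediction <- function(model, pset, tr, ext, cool_cache, rtol, atol) {
  cond <- attr(tr, "conditions")
  lo <- min(tr$temperature_C); hi <- max(tr$temperature_C)
  C_tot <- cond$C_tot
  cool_state <- function() {
    key <- sprintf("%.6g_%.6g", C_tot, cond$rate)
    got <- get0(key, envir = cool_cache)
    if (!is.null(got)) return(got)
    prog <- temperature_program(ramp_segment(hi, lo, cond$rate))
    y0 <- .resolve_init(model, "equilibrium", C_tot, hi)
    conc <- .integrate(model, y0, .program_matrix(prog),
                       c(0, prog$total_time), rtol, atol)
    st <- conc[2, seq_along(model$species)]
    st <- st * C_tot / sum(STRANDS[model$species] * st)
    assign(key, st, envir = cool_cache)
    st
  }
  if (identical(cond$direction, "cooling")) {
    prog <- temperature_program(ramp_segment(hi, lo, cond$rate))
    y0 <- .resolve_init(model, "equilibrium", C_tot, hi)
  } else {
    prog <- temperature_program(ramp_segment(lo, hi, cond$rate))
    proto <- cond$init_protocol %||% "anneal_same_rate"
    y0 <- switch(proto,
      anneal_same_rate = cool_state(),
      all_monomer = .resolve_init(model, "all_monomer", C_tot, lo),
      equilibrium = , equilibrium_at_start =
        .resolve_init(model, "equilibrium", C_tot, lo),
      stop("unknown init_protocol: ", proto))
  }
  conc <- .integrate(model, y0, .program_matrix(prog), tr$time_s, rtol, atol)
  states <- .full_species(conc, model$species)
  absorbance(states, kelvin_to_celsius(conc[, ncol(conc)]), ext)
}

#' Data-driven initial guess for a global fit
#'
#' Baselines are read off the trace extremes (the high-temperature ends of
#' all traces estimate the unfolded-strand coefficient line; the
#' low-temperature end of the slowest cooling trace bounds the folded one).
#' Kinetic parameters are anchored to two observable features: the
#' mid-transition temperature of the slowest cooling trace locates the
#' temperature where assembly is half-favourable at the working
#' concentration (each stepwise association constant is set to 10/C there
#' and extrapolated with generic step enthalpies of -30, -35 and -45
#' kcal/mol), and the ramp duration sets the association rate scale (an
#' assembly flux marginal on the annealing timescale, the regime in which
#' hysteresis is observed at all).
#'
#' @param model_name `"model1"` or `"model2"`
#' @param dataset a `th_dataset`
#' @param dialect extinction dialect to fit under
#' @return a [parameter_set()]
#' @export
initial_guess <- function(model_name, dataset, dialect = "midpoint") {
  conds <- lapply(dataset, attr, "conditions")
  pts <- do.call(rbind, lapply(seq_along(dataset), function(i)
    data.frame(T_C = dataset[[i]]$temperature_C,
               eps = dataset[[i]]$absorbance_AU /
                 (conds[[i]]$C_tot * conds[[i]]$path_length))))
  hiT <- pts[pts$T_C > max(pts$T_C) - 8, ]
  fitM <- stats::lm(eps ~ T_C, data = hiT)
  loT <- pts[pts$T_C < min(pts$T_C) + 5, ]
  epsT_int <- max(min(loT$eps) * 0.95, 1.1e3)

  # anchor trace: slowest cooling ramp at the median concentration
  is_cool <- vapply(conds, function(cc)
    identical(cc$direction, "cooling"), logical(1))
  cand <- if (any(is_cool)) which(is_cool) else seq_along(dataset)
  rates <- vapply(cand, function(i) conds[[i]]$rate %||% 1, numeric(1))
  anchor <- cand[which.min(rates)]
  C_anch <- conds[[anchor]]$C_tot
  Tm_C <- tryCatch(t_half(dataset[[anchor]]),
                   error = function(e) mean(range(pts$T_C)))
  Tm_K <- celsius_to_kelvin(Tm_C)

  # stepwise association constants: 10/C at the apparent midpoint,
  # extrapolated to T_ref with generic assembly enthalpies
  dH <- c(-30, -35, -45)
  K_ref <- vapply(dH, function(h)
    (10 / C_anch) * exp(-(h / RGAS) * (1 / 298.15 - 1 / Tm_K)), numeric(1))
  # association rate scale: marginal assembly over the anchor ramp time
  t_ramp <- max(dataset[[anchor]]$time_s)
  kf <- pmin(pmax(c(10, 1, 5) / (C_anch * t_ramp), 1e-3), 1e7)
  Ea_f <- c(5, 5, 5)
  steps <- lapply(1:3, function(i)
    rate_params(kf[i], Ea_f[i], kf[i] / K_ref[i], Ea_f[i] - dH[i]))
  if (model_name == "model2")
    steps <- c(steps, list(rate_params(3e-2, 10, 1.2e-3, 45)))
  parameter_set(steps,
                baseline = c(unname(stats::coef(fitM))[1],
                             unname(stats::coef(fitM))[2],
                             epsT_int, unname(stats::coef(fitM))[2] / 2),
                dialect = dialect)
}

# --- fused simulation + baseline profiling (variable projection) ---------
#
# Absorbance is linear in the four baseline coefficients, so for any kinetic
# parameter point the optimal baselines solve a 4-column linear least squares
# problem exactly. fit_global() therefore runs LM over the kinetic
# parameters only and profiles the baselines out at every evaluation -- the
# classic separable (variable projection) formulation.

# species trajectories for every trace, integrating each concentration/rate
# cell once (cooling ramp continued into the annealed heating ramp)
.sim_species_cells <- function(model, dataset, rtol, atol) {
  conds <- lapply(dataset, attr, "conditions")
  key <- vapply(conds, function(cc)
    sprintf("%.8g_%.8g", cc$C_tot, cc$rate), character(1))
  out <- vector("list", length(dataset))
  for (k in unique(key)) {
    idx <- which(key == k)
    cc <- conds[[idx[1]]]
    proto <- function(i) conds[[i]]$init_protocol %||% "anneal_same_rate"
    fused <- idx[vapply(idx, function(i)
      conds[[i]]$direction == "cooling" ||
        proto(i) == "anneal_same_rate", logical(1))]
    single <- setdiff(idx, fused)
    if (length(fused)) {
      tr1 <- dataset[[fused[1]]]
      lo <- min(tr1$temperature_C); hi <- max(tr1$temperature_C)
      cool_dur <- (hi - lo) / cc$rate * 60
      has_heat <- any(vapply(fused, function(i)
        conds[[i]]$direction == "heating", logical(1)))
      segs <- list(ramp_segment(hi, lo, cc$rate))
      if (has_heat) segs <- c(segs, list(ramp_segment(lo, hi, cc$rate)))
      prog <- temperature_program(segs)
      sched <- do.call(rbind, lapply(fused, function(i) {
        tt <- dataset[[i]]$time_s
        if (conds[[i]]$direction == "heating") tt <- tt + cool_dur
        data.frame(t = tt, trace = i, row = seq_along(tt))
      }))
      sched <- sched[order(sched$t), ]
      y0 <- .resolve_init(model, "equilibrium", cc$C_tot, hi)
      conc <- .integrate(model, y0, .program_matrix(prog), sched$t,
                         rtol, atol)
      states <- .full_species(conc, model$species)
      T_C <- kelvin_to_celsius(conc[, ncol(conc)])
      for (i in fused) {
        sel <- sched$trace == i
        ord <- order(sched$row[sel])
        rows <- which(sel)[ord]
        out[[i]] <- list(states = states[rows, , drop = FALSE],
                         T_C = T_C[rows])
      }
    }
    for (i in single) {
      tr <- dataset[[i]]
      lo <- min(tr$temperature_C); hi <- max(tr$temperature_C)
      prog <- temperature_program(ramp_segment(lo, hi, cc$rate))
      y0 <- .resolve_init(model, switch(proto(i),
                                        all_monomer = "all_monomer",
                                        "equilibrium"),
                          cc$C_tot, lo)
      conc <- .integrate(model, y0, .program_matrix(prog), tr$time_s,
                         rtol, atol)
      out[[i]] <- list(states = .full_species(conc, model$species),
                       T_C = kelvin_to_celsius(conc[, ncol(conc)]))
    }
  }
  out
}

# design matrix of the baseline regression for one trace
.baseline_design <- function(states, T_C, path_length, dialect) {
  if (dialect == "midpoint") {
    uM <- states[, "M"] + states[, "D"] + states[, "Dstar"] +
      0.75 * states[, "Tri"]
    uT <- states[, "D"] + states[, "Dstar"] + 2.25 * states[, "Tri"] +
      4 * states[, "T"]
  } else {
    uM <- states[, "M"]
    uT <- 2 * states[, "D"] + 2 * states[, "Dstar"] +
      3 * states[, "Tri"] + 4 * states[, "T"]
  }
  path_length * cbind(uM, uM * T_C, uT, uT * T_C)
}

# residuals with baselines profiled out; returns the vector with the fitted
# baseline coefficients as an attribute
.residuals_profiled <- function(model_name, steps, dataset, dialect,
                                rtol, atol) {
  n <- vapply(dataset, nrow, 1L)
  model <- try(build_model(model_name, steps), silent = TRUE)
  sims <- if (inherits(model, "try-error")) NULL
          else try(.sim_species_cells(model, dataset, rtol, atol),
                   silent = TRUE)
  if (is.null(sims) || inherits(sims, "try-error")) {
    r <- rep(1e3, sum(n))
    attr(r, "baseline") <- rep(NA_real_, 4)
    return(r)
  }
  X <- do.call(rbind, lapply(seq_along(dataset), function(i)
    .baseline_design(sims[[i]]$states, sims[[i]]$T_C,
                     attr(dataset[[i]], "conditions")$path_length, dialect)))
  y <- unlist(lapply(dataset, function(tr) tr$absorbance_AU),
              use.names = FALSE)
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) {
    r <- rep(1e3, sum(n))
    attr(r, "baseline") <- rep(NA_real_, 4)
    return(r)
  }
  r <- y - as.numeric(X %*% beta)
  attr(r, "baseline") <- as.numeric(beta)
  r
}

.pack_steps <- function(steps) {
  unlist(lapply(steps, function(p)
    c(log10(p$k_f_ref), p$Ea_f, log10(p$k_r_ref), p$Ea_r)))
}

.unpack_steps <- function(pvec, T_ref = 298.15) {
  n_steps <- length(pvec) %/% 4L
  lapply(seq_len(n_steps), function(i) {
    j <- 4 * (i - 1)
    rate_params(10^pvec[[j + 1]], pvec[[j + 2]], 10^pvec[[j + 3]],
                pvec[[j + 4]], T_ref = T_ref)
  })
}

# Levenberg-Marquardt least squares with box bounds (projected steps) and a
# forward-difference Jacobian on scaled parameters.
.lm_bounded <- function(resid_fn, p0, lower, upper, scale, max_iter = 80,
                        ftol = 1e-10, xtol = 1e-10, fd_rel = 1e-4,
                        verbose = FALSE) {
  p <- pmin(pmax(p0, lower), upper)
  r <- resid_fn(p)
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  npar <- length(p)
  for (iter in seq_len(max_iter)) {
    # Jacobian wrt scaled parameters z = p / scale
    J <- matrix(0, length(r), npar)
    for (j in seq_len(npar)) {
      dp <- fd_rel * scale[j]
      pj <- p
      pj[j] <- if (p[j] + dp <= upper[j]) p[j] + dp else p[j] - dp
      J[, j] <- (resid_fn(pj) - r) / ((pj[j] - p[j]) / scale[j])
    }
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    dJtJ <- diag(JtJ)
    dJtJ[dJtJ < 1e-12] <- 1e-12
    improved <- FALSE
    for (k in 1:12) {
      H <- JtJ + lambda * diag(dJtJ, npar)
      dz <- tryCatch(solve(H, -g), error = function(e) NULL)
      if (is.null(dz)) { lambda <- lambda * 10; next }
      pnew <- pmin(pmax(p + as.numeric(dz) * scale, lower), upper)
      rnew <- resid_fn(pnew)
      rssnew <- sum(rnew^2)
      if (is.finite(rssnew) && rssnew < rss) {
        step_sc <- max(abs((pnew - p) / scale))
        frel <- (rss - rssnew) / max(rss, 1e-300)
        p <- pnew; r <- rnew; rss <- rssnew
        lambda <- max(lambda / 4, 1e-12)
        improved <- TRUE
        if (frel < ftol || step_sc < xtol) converged <- TRUE
        break
      } else lambda <- lambda * 6
    }
    if (verbose) message(sprintf("  iter %2d rss %.6e lambda %.1e",
                                 iter, rss, lambda))
    if (!improved) { converged <- TRUE; break }
    if (converged) break
  }
  list(par = p, rss = rss, residuals = r, converged = converged,
       iterations = iter)
}

#' Globally fit one mechanism to a multi-condition TH dataset
#'
#' Levenberg-Marquardt least squares over the shared kinetic parameters
#' (log10 rate constants and linear activation energies), with the four
#' baseline coefficients profiled out exactly at every step (absorbance is
#' linear in them, so they solve a small linear least-squares problem --
#' variable projection). Best of `n_starts` starting points: start 1 is
#' `init` (defaulting to [initial_guess()]), the rest are seeded uniform
#' draws inside the bounds (log-uniform in the rate constants, which are
#' bounded in log10 space). Deterministic for a given seed. `n_params`
#' counts all free parameters, kinetic plus baseline.
#'
#' @param model_name `"model1"` or `"model2"`
#' @param dataset a `th_dataset`
#' @param init optional [parameter_set()] (or list of them) used as the
#'   first start(s)
#' @param bounds list with `lower`/`upper` packed vectors
#'   (default [default_bounds()])
#' @param n_starts number of starting points (>= 1)
#' @param seed RNG seed for the random starts
#' @param max_iter LM iteration cap per start
#' @param rtol,atol integrator tolerances used in the objective
#' @param dialect extinction dialect shared by all traces
#' @param fixed optional kinetic parameters to hold at their start values:
#'   a logical mask over the packed kinetic vector or a character vector of
#'   its names (e.g. `"log10_kf_2"`); used for staged refinements
#' @param verbose print per-iteration progress
#' @return object of class `fit_result`: `params`, `rss`, `n_points`,
#'   `n_params`, `converged`, `residuals_by_trace`, `model_name`
#' @export
fit_global <- function(model_name = c("model1", "model2"), dataset,
                       init = NULL, bounds = default_bounds(model_name),
                       n_starts = 8L, seed = 1L, max_iter = 80L,
                       rtol = 1e-6, atol = 1e-10, dialect = "midpoint",
                       fixed = NULL, verbose = FALSE) {
  model_name <- match.arg(model_name)
  stopifnot(n_starts >= 1L)
  n_steps <- if (model_name == "model1") 3L else 4L
  if (is.null(init)) init <- initial_guess(model_name, dataset, dialect)
  inits <- if (inherits(init, "parameter_set")) list(init) else init
  n_points <- sum(vapply(dataset, nrow, 1L))
  n_params <- 4L * n_steps + 4L
  if (n_points <= n_params)
    stop("dataset has ", n_points, " points but the model has ", n_params,
         " free parameters")

  # kinetic block only: baselines are profiled out (variable projection)
  kin <- seq_len(4L * n_steps)
  lower <- bounds$lower[kin]; upper <- bounds$upper[kin]
  scale <- rep(c(1, 10, 1, 10), n_steps)
  kin_names <- names(lower)

  free <- rep(TRUE, length(kin))
  if (!is.null(fixed)) {
    if (is.character(fixed)) fixed <- kin_names %in% fixed
    stopifnot(length(fixed) == length(kin))
    free <- !fixed
    if (!any(free)) stop("all kinetic parameters fixed")
  }

  resid_full <- function(pvec) {
    steps <- try(.unpack_steps(pvec), silent = TRUE)
    if (inherits(steps, "try-error")) return(rep(1e3, n_points))
    .residuals_profiled(model_name, steps, dataset, dialect, rtol, atol)
  }

  starts <- lapply(inits, function(ii) .pack_steps(ii$steps))
  if (n_starts > length(starts)) {
    set.seed(seed)
    for (s in (length(starts) + 1L):n_starts)
      starts[[s]] <- setNames(runif(length(kin), lower, upper), kin_names)
  }

  best <- NULL
  for (s in seq_along(starts)) {
    if (verbose) message("start ", s, "/", length(starts))
    p0 <- starts[[s]]
    resid_fn <- function(pfree) {
      pv <- p0; pv[free] <- pfree
      resid_full(pv)
    }
    fit <- .lm_bounded(resid_fn, p0[free], lower[free], upper[free],
                       scale[free],
                       max_iter = if (s <= length(inits)) max_iter
                                  else max(20L, max_iter %/% 2L),
                       verbose = verbose)
    fit$par_full <- p0
    fit$par_full[free] <- fit$par
    if (is.null(best) || fit$rss < best$rss) best <- fit
  }
  if (is.null(best)) stop("no start converged")
  best$par <- best$par_full

  r <- resid_full(best$par)
  beta <- attr(r, "baseline")
  if (any(!is.finite(beta)))
    stop("fit did not reach a simulable parameter point; best rss = ",
         signif(best$rss, 6))
  pset <- parameter_set(.unpack_steps(best$par), baseline = beta,
                        dialect = dialect)
  n <- vapply(dataset, nrow, 1L)
  by_trace <- split(as.numeric(r), rep(seq_along(dataset), n))
  names(by_trace) <- names(dataset)
  structure(list(params = pset, rss = sum(r^2), n_points = n_points,
                 n_params = n_params, converged = best$converged,
                 iterations = best$iterations,
                 residuals_by_trace = by_trace,
                 model_name = model_name),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: rss = %.6g AU^2, n = %d, p = %d, %s>\n",
              x$model_name, x$rss, x$n_points, x$n_params,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
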