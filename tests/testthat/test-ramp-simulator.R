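test_that("temperature programs validate and time segments correctly", {
  prog <- temperature_program(ramp_segment(85, 5, 0.5),
                              hold_segment(5, 600),
                              ramp_segment(5, 85, 5))
  expect_equal(prog$total_time, 80 / 0.5 * 60 + 600 + 80 / 5 * 60)
  expect_error(ramp_segment(85, 5, 0), "rate > 0")
  expect_error(ramp_segment(85, 120, 1), "sane")
  expect_error(hold_segment(25, 0), "duration > 0")
})

test_that("frozen kinetics give a pure monomer baseline trace", {
  m0 <- build_model("model2") # inert rates
  prog <- temperature_program(ramp_segment(85, 5, 5))
  tr <- simulate_program(m0, prog, 1e-4, "all_monomer", ext_truth)
  expect_equal(tr$M, rep(1e-4, nrow(tr)))
  epsM <- truth2$baseline[1] + truth2$baseline[2] * tr$temperature_C
  expect_equal(tr$absorbance_AU, epsM * 1e-4 * 0.1, tolerance = 1e-10)
})

test_that("irreversible dimerisation matches the closed form to 1e-6", {
  m <- build_model("model1", list(rate_params(1e3, 0, 0, 0),
                                  rate_params(0, 0, 0, 0),
                                  rate_params(0, 0, 0, 0)))
  ic <- isothermal_course(m, 25, 1e-4, "all_monomer", duration = 10,
                          n_out = 21, log_time = FALSE,
                          rtol = 1e-11, atol = 1e-16, method = "kr4")
  expect_equal(ic$M[21], dimer_decay_oracle(1e-4, 1e3, 10),
               tolerance = 1e-6)
  # [M](10 s) = 33.33 uM for [M]0 = 100 uM (strand), k = 1e3
  expect_equal(ic$M[21] * 1e6, 33.3333, tolerance = 1e-4)
})

test_that("2M = D equilibrium matches the quadratic closed form to 1e-10", {
  m <- build_model("model1", list(rate_params(1e4, 0, 1, 0),
                                  rate_params(0, 0, 0, 0),
                                  rate_params(0, 0, 0, 0)))
  st <- equilibrium_state(m, 298.15, 1e-4)
  expect_equal(st[["M"]], dimer_eq_oracle(1e4, 1e-4), tolerance = 1e-10)
  expect_equal(st[["M"]], 5e-5, tolerance = 1e-10)
  expect_equal(st[["D"]], 2.5e-5, tolerance = 1e-10)
  expect_equal(strand_total(st), 1e-4, tolerance = 1e-12)
})

test_that("equilibrium solver satisfies detailed balance", {
  for (tc in c(10, 40, 70)) {
    st <- equilibrium_state(model2, celsius_to_kelvin(tc), 5e-5)
    flux <- imotifTH:::.step_fluxes(model2, st, celsius_to_kelvin(tc))
    gross <- vapply(model2$steps, function(s)
      arrhenius_rate(s$params, "forward", celsius_to_kelvin(tc)) *
        prod(st[s$reactants]), numeric(1))
    expect_true(all(abs(flux) < 1e-10 * pmax(gross, 1e-300)))
  }
})

test_that("trap equilibrium ratio is concentration independent", {
  Tk <- celsius_to_kelvin(20)
  r <- vapply(c(2e-5, 5e-5, 2.5e-4), function(C) {
    st <- equilibrium_state(model2, Tk, C)
    st[["Dstar"]] / st[["D"]]
  }, numeric(1))
  expect_equal(r[1], r[2], tolerance = 1e-9)
  expect_equal(r[2], r[3], tolerance = 1e-9)
  # and equals K_trap(T)
  s4 <- model2$steps[[4]]$params
  expect_equal(r[1], arrhenius_rate(s4, "forward", Tk) /
                       arrhenius_rate(s4, "reverse", Tk), tolerance = 1e-9)
})

test_that("equilibrium_state refuses irreversible steps", {
  m <- build_model("model1", list(rate_params(1e4, 0, 0, 0),
                                  rate_params(1, 0, 1, 0),
                                  rate_params(1, 0, 1, 0)))
  expect_error(equilibrium_state(m, 298.15, 1e-4), "irreversible")
})

test_that("absorbance follows the dialect rules and hypochromicity", {
  ex <- extinction_model(1.0, 0, 0.5, 0, dialect = "midpoint",
                         path_length = 1)
  # dimer per strand sits half-way: (1 + 0.5)/2 = 0.75
  A_D <- absorbance(species_state(D = 1), 25, ex)
  expect_equal(A_D, 2 * 0.75)
  A_Tri <- absorbance(species_state(Tri = 1), 25, ex)
  expect_equal(A_Tri, 3 * (1 + 3 * 0.5) / 4)
  expect_equal(absorbance(species_state(Dstar = 1), 25, ex), A_D)
  # tetramer_fraction: per complex half / three quarters of the tetramer
  exf <- extinction_model(1.0, 0, 0.5, 0, dialect = "tetramer_fraction",
                          path_length = 1)
  expect_equal(absorbance(species_state(D = 1), 25, exf), 0.5 * 4 * 0.5)
  expect_equal(absorbance(species_state(Tri = 1), 25, exf), 0.75 * 4 * 0.5)
  # folding decreases absorbance at matched strand totals
  A_mono <- absorbance(species_state(M = 4e-5), 25, ext_truth)
  A_tet <- absorbance(species_state(T = 1e-5), 25, ext_truth)
  expect_lt(A_tet, A_mono)
})

test_that("extinction_model enforces its invariants", {
  expect_error(extinction_model(4e4, 0, 5e4, 0, dialect = "midpoint"),
               "hypochromicity", ignore.case = TRUE)
  expect_error(extinction_model(1e3, -100, 5e2, 0, dialect = "midpoint"),
               "positive")
  expect_message(extinction_model(5e4, 0, 4e4, 0), "midpoint")
})

test_that("simulate_program rejects an init inconsistent with C_tot", {
  expect_error(
    simulate_program(model2, temperature_program(ramp_segment(85, 5, 5)),
                     5e-5, species_state(M = 6e-5), ext_truth),
    "does not match C_tot")
})

test_that("strand mass is conserved along ramped trajectories", {
  tr <- simulate_ramp(model2, "cooling", 5, 5e-5, ext_truth)
  tot <- tr$M + 2 * tr$D + 2 * tr$Dstar + 3 * tr$Tri + 4 * tr$T
  expect_lt(max(abs(tot - 5e-5)) / 5e-5, 1e-6)
  tr2 <- simulate_ramp(model1, "heating", 0.5, 2.5e-4, ext_truth)
  tot2 <- tr2$M + 2 * tr2$D + 3 * tr2$Tri + 4 * tr2$T
  expect_lt(max(abs(tot2 - 2.5e-4)) / 2.5e-4, 1e-6)
  ic <- isothermal_course(model2, 4, 5e-5, "all_monomer", 86400)
  tot3 <- ic$frac_M + ic$frac_D + ic$frac_Dstar + ic$frac_Tri + ic$frac_T
  expect_lt(max(abs(tot3 - 1)), 1e-6)
})

test_that("halving the tolerances changes absorbance by < 1e-5 AU", {
  a <- simulate_ramp(model2, "cooling", 5, 5e-5, ext_truth,
                     rtol = 1e-7, atol = 1e-11, keep_species = FALSE)
  b <- simulate_ramp(model2, "cooling", 5, 5e-5, ext_truth,
                     rtol = 5e-8, atol = 5e-12, keep_species = FALSE)
  expect_lt(max(abs(a$absorbance_AU - b$absorbance_AU)), 1e-5)
})

test_that("the two integrator schemes agree on a stiff ramp", {
  prog <- temperature_program(ramp_segment(85, 5, 5))
  y0 <- imotifTH:::.resolve_init(model2, "equilibrium", 5e-5, 85)
  out_t <- imotifTH:::.program_out_times(prog, 0.5)
  pm <- imotifTH:::.program_matrix(prog)
  cr <- imotifTH:::.integrate(model2, y0, pm, out_t, 1e-8, 1e-12, "rodas3")
  ck <- imotifTH:::.integrate(model2, y0, pm, out_t, 1e-8, 1e-12, "kr4")
  expect_lt(max(abs(cr - ck)), 1e-9)
})

test_that("compiled core agrees with a pure-R RK4 over rate_of_change", {
  # dual route: integrate a mildly stiff random network for 5 s with a
  # fixed-step classical RK4 driven by the R rate law, and compare the
  # compiled adaptive Rosenbrock result
  rk4 <- function(m, st, Tk, t_end, n_steps) {
    h <- t_end / n_steps
    y <- st
    f <- function(y) rate_of_change(m, pmax(y, 0), Tk)
    for (i in seq_len(n_steps)) {
      k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
      k4 <- f(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  set.seed(7)
  for (i in 1:3) {
    ps <- replicate(4, rate_params(10^runif(1, 1, 3), runif(1, 0, 30),
                                   10^runif(1, -3, -1), runif(1, 0, 40)),
                    simplify = FALSE)
    m <- build_model("model2", ps)
    st <- species_state(M = 1e-4)
    Tk <- runif(1, 280, 350)
    y_ref <- rk4(m, unclass(st), Tk, 5, 8000)
    seg <- matrix(c(0, 5, Tk, 0), 1)
    conc <- imotifTH:::.integrate(m, as.numeric(st[m$species]), seg,
                                  c(0, 5), 1e-9, 1e-15)
    y_cpp <- conc[2, seq_along(m$species)]
    expect_lt(max(abs(y_cpp - y_ref[m$species])) / 1e-4, 2e-6)
  }
})

test_that("isothermal_course reports the expected event ordering", {
  expect_error(isothermal_course(model2, 25, 5e-5, "all_monomer", -1))
  # frozen kinetics: fractions constant
  ic0 <- isothermal_course(build_model("model1"), 25, 5e-5, "all_monomer",
                           3600, n_out = 20)
  expect_true(all(ic0$frac_M == 1))
  # fast dimerisation, slow trimer step: transient dimer maximum before the
  # tetramer accumulates
  m <- build_model("model1", list(rate_params(1e4, 0, 1e-2, 0),
                                  rate_params(1e1, 0, 1e-6, 0),
                                  rate_params(1e4, 0, 1e-6, 0)))
  ic <- isothermal_course(m, 25, 1e-4, "all_monomer", 2e5, n_out = 300)
  i_dmax <- which.max(ic$frac_D)
  expect_gt(ic$frac_D[i_dmax], 0.5)
  expect_lt(ic$frac_T[i_dmax], 0.2)
  expect_gt(tail(ic$frac_T, 1), ic$frac_D[i_dmax])
  # fast trap in, slow trap out: Dstar exceeds T over a finite horizon
  m2 <- build_model("model2", list(rate_params(1e4, 0, 1e-2, 0),
                                   rate_params(1e1, 0, 1e-6, 0),
                                   rate_params(1e4, 0, 1e-6, 0),
                                   rate_params(1e-1, 0, 1e-6, 0)))
  ic2 <- isothermal_course(m2, 25, 1e-4, "all_monomer", 1e4, n_out = 200)
  expect_gt(tail(ic2$frac_Dstar, 1), tail(ic2$frac_T, 1))
})

test_that("hysteresis width behaves at its limits", {
  heat <- simulate_ramp(model1, "heating", 5, 2.5e-4, ext_truth,
                        keep_species = FALSE)
  expect_equal(hysteresis_width(heat, heat), 0)
  cool <- simulate_ramp(model1, "cooling", 5, 2.5e-4, ext_truth,
                        keep_species = FALSE)
  expect_gt(hysteresis_width(heat, cool), 0)
  # equilibrium curve as the zero-rate annealing reference
  eq <- equilibrium_curve(model1, 2.5e-4, ext_truth, grid_C = 1)
  expect_gt(hysteresis_width(heat, eq), 0)
  bad <- eq[eq$temperature_C > 80, ]
  attr(bad, "conditions") <- attr(eq, "conditions")
  expect_error(hysteresis_width(heat, bad), "overlap")
})
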