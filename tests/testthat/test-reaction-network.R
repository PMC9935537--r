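test_that("arrhenius_rate matches the closed form and its limits", {
  # temperature-independent limit and identity at the reference temperature
  rp0 <- rate_params(k_f_ref = 3.7, Ea_f = 0, k_r_ref = 0.2, Ea_r = 0)
  expect_equal(arrhenius_rate(rp0, "forward", 250), 3.7)
  expect_equal(arrhenius_rate(rp0, "reverse", 350), 0.2)
  rp <- rate_params(k_f_ref = 1e3, Ea_f = 20, k_r_ref = 1e-2, Ea_r = 55)
  expect_equal(arrhenius_rate(rp, "forward", rp$T_ref), 1e3)
  # independent high-precision evaluation at T = 308.15 K
  expect_equal(arrhenius_rate(rp, "forward", 308.15),
               arrhenius_oracle(1e3, 20, 298.15, 308.15), tolerance = 1e-12)
  expect_equal(arrhenius_rate(rp, "forward", 308.15), 2990.513,
               tolerance = 1e-6)
  # vectorised over T
  expect_length(arrhenius_rate(rp, "reverse", c(280, 300, 320)), 3L)
  expect_error(arrhenius_rate(rp, "forward", -5), "positive")
  expect_error(arrhenius_rate(rp, "forward", 0), "positive")
})

test_that("rate_params validates its inputs", {
  expect_error(rate_params(-1, 10, 1, 10), "nonnegative")
  expect_error(rate_params(1, 10, -1, 10), "nonnegative")
  expect_error(rate_params(1, 10, 1, 10, T_ref = 0), "T_ref")
})

test_that("build_model constructs the two nested mechanisms", {
  m1 <- build_model("model1")
  expect_identical(m1$species, c("M", "D", "Tri", "T"))
  expect_length(m1$steps, 3L)
  m2 <- build_model("model2")
  expect_identical(m2$species, c("M", "D", "Dstar", "Tri", "T"))
  expect_length(m2$steps, 4L)
  expect_identical(m2$steps[[4]]$reactants, "D")
  expect_identical(m2$steps[[4]]$products, "Dstar")
  expect_error(build_model("model3"))
  expect_error(build_model("model1", truth2$steps), "exactly 3")
})

test_that("model2 with a silenced trap reproduces model1 dynamics", {
  steps2 <- c(truth1$steps, list(rate_params(0, 0, 0, 0)))
  m2 <- build_model("model2", steps2)
  prog <- temperature_program(ramp_segment(85, 25, 5))
  tr1 <- simulate_program(model1, prog, 5e-5, "all_monomer", ext_truth)
  tr2 <- simulate_program(m2, prog, 5e-5, "all_monomer", ext_truth)
  for (sp in c("M", "D", "Tri", "T"))
    expect_lt(max(abs(tr2[[sp]] - tr1[[sp]])), 1e-8) # M, ~2e-4 of C_tot
  expect_true(all(tr2$Dstar == 0))
  expect_lt(max(abs(tr2$absorbance_AU - tr1$absorbance_AU)), 1e-6)
})

test_that("rate_of_change applies mass-action stoichiometry", {
  # only M+M -> D active, k_f = 1e3, [M] = 1e-4: event rate 1e-5 M/s
  m <- build_model("model1", list(rate_params(1e3, 0, 0, 0),
                                  rate_params(0, 0, 0, 0),
                                  rate_params(0, 0, 0, 0)))
  d <- rate_of_change(m, species_state(M = 1e-4), 298.15)
  expect_equal(d[["M"]], -2e-5)
  expect_equal(d[["D"]], 1e-5)
  expect_equal(unname(d[c("Dstar", "Tri", "T")]), c(0, 0, 0))
  # all rate constants zero -> all derivatives zero
  m0 <- build_model("model2")
  d0 <- rate_of_change(m0, random_state(), 300)
  expect_true(all(d0 == 0))
  expect_error(rate_of_change(m, species_state(M = 1e-4) - 2e-4, 298.15))
})

test_that("strand mass derivative is exactly zero (stoichiometry property)", {
  strands <- c(M = 1, D = 2, Dstar = 2, Tri = 3, T = 4)
  set.seed(42)
  for (i in 1:25) {
    m <- random_model(sample(c("model1", "model2"), 1))
    d <- rate_of_change(m, random_state(), runif(1, 270, 370))
    expect_lt(abs(sum(strands * d)), 1e-12 * max(abs(d), 1))
  }
})

test_that("strand_total counts strands per complex", {
  expect_equal(strand_total(species_state(M = 1e-5, D = 5e-6)), 2e-5)
  expect_equal(strand_total(species_state()), 0)
  # 12.5 uM pure tetramer is 50 uM strand, the standard low concentration
  expect_equal(strand_total(species_state(T = 12.5e-6)), 50e-6)
})

test_that("reaction_step enforces strand conservation", {
  expect_error(reaction_step(c("M", "M"), "Tri", random_params()),
               "strand count")
  expect_error(reaction_step("D", "T", random_params()), "strand count")
  st <- reaction_step(c("Tri", "M"), "T", random_params())
  expect_equal(st$molecularity_f, 2L)
})

test_that("species_state rejects unphysical input", {
  expect_error(species_state(M = -1e-6), "nonnegative")
  expect_error(species_state(M = NaN), "nonnegative")
})

test_that("model JSON round trip preserves the network", {
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model2, path)
  m <- model_from_json(path)
  expect_identical(m$name, "model2")
  expect_identical(m$species, model2$species)
  for (i in seq_along(m$steps))
    expect_equal(unclass(m$steps[[i]]$params),
                 unclass(model2$steps[[i]]$params))
})
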