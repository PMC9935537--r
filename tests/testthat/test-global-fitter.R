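# Fitting tests use a reduced two-trace-per-cell design on a coarse (1 degC)
# grid so the whole file stays fast; the full-design, full-resolution fits
# live in test-acceptance.R.

test_that("residual vector concatenates all traces in order", {
  des <- experiment_design(concentrations_uM = c(50, 250), rates = 0.5,
                           noise_sigma = 0, grid_C = 0.25, seed = 1)
  ds <- generate_dataset("model2", design = des)
  r <- residuals_global("model2", truth2, ds)
  expect_length(r, 4 * 321)
  bt <- attr(r, "by_trace")
  expect_length(bt, 4L)
  expect_identical(names(bt), names(ds))
})

test_that("noiseless data give residuals at integrator precision", {
  des <- experiment_design(rates = 5, noise_sigma = 0, grid_C = 1, seed = 1)
  ds <- generate_dataset("model2", design = des, rtol = 1e-9, atol = 1e-13)
  r <- residuals_global("model2", truth2, ds, rtol = 1e-9, atol = 1e-13)
  expect_lt(max(abs(r)), 1e-8)
})

test_that("an additive offset on one trace shifts only its residuals", {
  des <- experiment_design(rates = 5, noise_sigma = 0, grid_C = 2, seed = 1)
  ds <- generate_dataset("model2", design = des, rtol = 1e-8, atol = 1e-12)
  r0 <- residuals_global("model2", truth2, ds, rtol = 1e-8, atol = 1e-12)
  delta <- 0.05
  ds[[2]]$absorbance_AU <- ds[[2]]$absorbance_AU + delta
  r1 <- residuals_global("model2", truth2, ds, rtol = 1e-8, atol = 1e-12)
  b0 <- attr(r0, "by_trace"); b1 <- attr(r1, "by_trace")
  expect_equal(b1[[2]] - b0[[2]], rep(delta, length(b0[[2]])))
  expect_equal(b1[[1]], b0[[1]])
  expect_equal(b1[[4]], b0[[4]])
})

test_that("rss is invariant under trace permutation", {
  des <- experiment_design(rates = 5, noise_sigma = 0.002, grid_C = 2,
                           seed = 3)
  ds <- generate_dataset("model2", design = des)
  r <- residuals_global("model2", truth2, ds)
  perm <- rev(seq_along(ds))
  dsp <- structure(unclass(ds)[perm], class = "th_dataset",
                   manifest = attr(ds, "manifest")[perm, ])
  rp <- residuals_global("model2", truth2, dsp)
  expect_identical(sum(r^2), sum(rp^2))
})

test_that("unsimulable parameter points yield penalty residuals, or raise in strict mode", {
  des <- experiment_design(rates = 5, noise_sigma = 0, grid_C = 4, seed = 1)
  ds <- generate_dataset("model2", design = des)
  bad <- truth2
  bad$baseline <- c(1e3, 0, 5e4, 0) # violates hypochromicity
  w <- capture_warnings(r <- residuals_global("model2", bad, ds))
  expect_match(w, "penalty", all = FALSE)
  expect_true(all(r == 1e3))
  expect_error(suppressWarnings(
    residuals_global("model2", bad, ds, strict = TRUE)))
})

test_that("fit_global refuses an under-determined dataset", {
  des <- experiment_design(concentrations_uM = 50, rates = 5,
                           directions = "cooling", noise_sigma = 0,
                           grid_C = 20, seed = 1)
  ds <- generate_dataset("model2", design = des) # 5 points < 20 params
  expect_error(fit_global("model2", ds), "free parameters")
})

test_that("fitting a nested pair on model1 data cannot favour the special case", {
  des <- small_design(sigma = 0.002, seed = 21, grid_C = 2)
  ds <- generate_dataset("model1", design = des)
  cmp <- suppressWarnings(
    compare_models(ds, n_starts = 1, init1 = truth1, max_iter = 60))
  expect_lte(cmp$fit2$rss, cmp$fit1$rss)
  expect_gte(cmp$ftest$p, 0)
  expect_identical(cmp$ftest$df1, 4L)
})

test_that("refitting from the optimum is a fixed point", {
  des <- small_design(sigma = 0.002, seed = 22, grid_C = 2)
  ds <- generate_dataset("model1", design = des)
  f1 <- suppressWarnings(fit_global("model1", ds, init = truth1,
                                    n_starts = 1, max_iter = 80))
  f2 <- suppressWarnings(fit_global("model1", ds, init = f1$params,
                                    n_starts = 1, max_iter = 20))
  expect_lte(f2$rss, f1$rss * (1 + 1e-12))
  expect_lt((f1$rss - f2$rss) / f1$rss, 1e-4)
})

test_that("initial_guess reads plausible baselines off the data", {
  des <- small_design(sigma = 0.002, seed = 23, grid_C = 1)
  ds <- generate_dataset("model2", design = des)
  g <- initial_guess("model2", ds)
  # unfolded-strand coefficient near its true line (a few percent)
  eM_true <- truth2$baseline[1] + truth2$baseline[2] * 80
  eM_guess <- g$baseline[1] + g$baseline[2] * 80
  expect_lt(abs(eM_guess - eM_true) / eM_true, 0.05)
  expect_length(g$steps, 4L)
})

test_that("parameter packing round-trips", {
  v <- imotifTH:::.pack_params(truth2)
  p2 <- imotifTH:::.unpack_params(v, 4L, dialect = truth2$dialect)
  for (i in 1:4)
    expect_equal(unclass(p2$steps[[i]]), unclass(truth2$steps[[i]]),
                 tolerance = 1e-12)
  expect_equal(unname(p2$baseline), unname(truth2$baseline))
})
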