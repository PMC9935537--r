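# Independent numerical oracles and shared fixtures for the test suite.
# Everything here is deliberately written from first principles (closed
# forms, continued fractions, brute-force sums) so it does not share code
# paths with the package internals it checks.

R_GAS <- 1.98720425e-3 # kcal mol^-1 K^-1

# regularized incomplete beta function I_x(a, b) by the standard
# Lentz continued-fraction expansion (independent of stats::pbeta)
betacf_oracle <- function(a, b, x) {
  qab <- a + b; qap <- a + 1; qam <- a - 1
  c <- 1; d <- 1 - qab * x / qap
  if (abs(d) < 1e-300) d <- 1e-300
  d <- 1 / d; h <- d
  for (m in 1:300) {
    m2 <- 2 * m
    aa <- m * (b - m) * x / ((qam + m2) * (a + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-300) d <- 1e-300
    c <- 1 + aa / c; if (abs(c) < 1e-300) c <- 1e-300
    d <- 1 / d; h <- h * d * c
    aa <- -(a + m) * (qab + m) * x / ((a + m2) * (qap + m2))
    d <- 1 + aa * d; if (abs(d) < 1e-300) d <- 1e-300
    c <- 1 + aa / c; if (abs(c) < 1e-300) c <- 1e-300
    d <- 1 / d
    del <- d * c; h <- h * del
    if (abs(del - 1) < 1e-15) break
  }
  h
}

ibeta_oracle <- function(a, b, x) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lbt <- lgamma(a + b) - lgamma(a) - lgamma(b) + a * log(x) + b * log1p(-x)
  if (x < (a + 1) / (a + b + 2))
    exp(lbt) * betacf_oracle(a, b, x) / a
  else
    1 - exp(lbt) * betacf_oracle(b, a, 1 - x) / b
}

# upper-tail probability of the F(df1, df2) distribution
f_pvalue_oracle <- function(F, df1, df2) {
  ibeta_oracle(df2 / 2, df1 / 2, df2 / (df2 + df1 * F))
}

# closed-form irreversible dimerisation decay, dM/dt = -2 k M^2
dimer_decay_oracle <- function(M0, k, t) M0 / (1 + 2 * k * M0 * t)

# closed-form 2M = D equilibrium under the strand constraint
# M + 2 K M^2 = C  ->  M = (-1 + sqrt(1 + 8 K C)) / (4 K)
dimer_eq_oracle <- function(K, C) (-1 + sqrt(1 + 8 * K * C)) / (4 * K)

# hand-rolled Arrhenius evaluation (same formula, separate code)
arrhenius_oracle <- function(k_ref, Ea, T_ref, T) {
  k_ref * exp(-(Ea / R_GAS) * (1 / T - 1 / T_ref))
}

# ---- shared fixtures (built once per test file) --------------------------

truth2 <- imotifTH::default_truth("model2")
truth1 <- imotifTH::default_truth("model1")
model2 <- imotifTH::build_model("model2", truth2$steps)
model1 <- imotifTH::build_model("model1", truth1$steps)
ext_truth <- imotifTH::extinction_model(
  truth2$baseline[1], truth2$baseline[2],
  truth2$baseline[3], truth2$baseline[4],
  dialect = "midpoint", path_length = 0.1)

# a small (single-concentration, single-rate) design for fast fitting tests
small_design <- function(sigma = 0.002, seed = 1L, grid_C = 1)
  imotifTH::experiment_design(concentrations_uM = c(50, 250),
                              rates = 2, noise_sigma = sigma,
                              grid_C = grid_C, seed = seed)

# random mass-action state/parameters for property tests
random_state <- function() {
  x <- runif(5, 0, 1e-4)
  imotifTH::species_state(M = x[1], D = x[2], Dstar = x[3],
                          Tri = x[4], T = x[5])
}

random_params <- function() {
  imotifTH::rate_params(k_f_ref = 10^runif(1, -2, 4),
                        Ea_f = runif(1, 0, 40),
                        k_r_ref = 10^runif(1, -6, 1),
                        Ea_r = runif(1, 0, 60))
}

random_model <- function(name = "model2") {
  n <- if (name == "model1") 3 else 4
  imotifTH::build_model(name, replicate(n, random_params(),
                                        simplify = FALSE))
}
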