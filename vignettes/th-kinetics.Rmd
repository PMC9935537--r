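---
title: "Thermal-hysteresis kinetics of tetramolecular i-motif assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-hysteresis kinetics of tetramolecular i-motif assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tetramolecular i-motifs assemble from four cytosine-rich strands through
dimeric and trimeric intermediates. Because association and dissociation are
slow compared with practical temperature ramps, UV melting experiments on
such systems show *thermal hysteresis* (TH): the heating (melting) trace
lies above the cooling (annealing) trace, and neither reflects equilibrium.
Far from being a nuisance, the rate- and concentration-dependence of that
hysteresis encodes the assembly kinetics. When chemically modified strands
can also fold into a stable *off-pathway dimeric i-motif*, the folding
landscape becomes kinetically partitioned: a fast-forming dimeric trap
competes with the thermodynamically favoured tetramer and slows its
assembly by orders of magnitude.

`imotifTH` implements the full analysis chain for such experiments:

1. mass-action reaction networks for the two candidate mechanisms
   (`build_model()`): sequential assembly `M+M = D`, `D+M = Tri`,
   `Tri+M = T` ("model1"), optionally extended by the unimolecular trap
   step `D = Dstar` ("model2", strictly nesting model1);
2. stiff ODE integration of those networks along temperature programs and
   conversion of populations to 265 nm absorbance (`simulate_ramp()`,
   `simulate_program()`, `isothermal_course()`);
3. global nonlinear least-squares fitting of shared kinetic and baseline
   parameters across multi-condition trace sets (`fit_global()`);
4. nested-model comparison by F-test (`f_test()`, `compare_models()`);
5. a synthetic-data generator with the statistical structure of the
   standard experiment (`generate_dataset()`), so that the whole chain is
   testable without instrument data.

## Model and rate law

Each elementary step is reversible with Arrhenius temperature dependence
around a reference temperature (298.15 K by default):

$$k(T) = k_\mathrm{ref}\, \exp\!\left[-\frac{E_a}{R}\left(\frac 1T -
\frac 1{T_\mathrm{ref}}\right)\right],$$

with $R = 1.98720425\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. The step
enthalpy is $\Delta H^\circ = E_{a,f} - E_{a,r}$ and the equilibrium
constant $K(T) = k_f(T)/k_r(T)$. An Eyring parameterisation would fit the
same data equally well; Arrhenius with a reference temperature was chosen
because it keeps every parameter a directly interpretable rate constant and
is the standard form in TH analyses of quadruplex association. Activation
energies are fitted in linear space bounded to 0–100 kcal/mol, rate
constants in log10 space — the two groups differ by many orders of
magnitude in scale.

Species concentrations are *complex* molarities internally; user-facing
totals are *strand* molarities ($C_\mathrm{tot} = [M] + 2[D] + 2[D^*] +
3[Tri] + 4[T]$), matching how oligonucleotide concentrations are reported.
Temperatures are Kelvin internally and Celsius at every interface.

The trap attaches as a unimolecular isomerisation of the on-pathway dimer
(`D = Dstar`), not as an independent `2M = Dstar` association: the
off-pathway species is a folded rearrangement of the dimeric intermediate.
There is no `D + D = T` channel; assembly is strictly by monomer addition.
pH is not modelled explicitly — the acidic condition that makes C:C+ pairs
possible is folded into the effective rate constants.

## Absorbance model

Folded i-motifs are hypochromic at 265 nm. The monomer (unfolded strand)
and tetramer carry per-strand extinction coefficients linear in
temperature (the sloping baselines of a melting trace); intermediate
species are derived from those two endpoint lines according to a
`dialect`:

* **midpoint** (default): the dimer — and the trap, which is spectrally
  indistinguishable from it — absorbs half-way between monomer and
  tetramer per strand; the trimer one quarter of the way up.
* **tetramer_fraction**: per complex, the dimer absorbs half and the
  trimer three quarters of the tetramer complex.

Both conventions appear in the TH literature (sometimes in the same
paper); neither is asserted to be "the" correct one, both are implemented,
and the choice is logged whenever it is left to default. The dimer and
trimer coefficients carry no slope parameters of their own — a deliberate
minimal parameterisation: four baseline parameters are already at the edge
of what a trace set constrains.

Absorbance is Beer–Lambert over all species,
$A = l \sum_i \epsilon_i(T)\, n_i [S_i]$, with $n_i$ the strand count.
Since $A$ is *linear* in the four baseline coefficients, the fitter
profiles them out exactly at every kinetic parameter point (variable
projection): the nonlinear search runs over the 12 (model1) or 16 (model2)
kinetic parameters only, which is both faster and far better conditioned.
The profiled baselines are unconstrained in that inner solve; hypochromicity
of the result is not enforced during fitting (it is checked when an
`extinction_model` is constructed explicitly).

## Numerical integration

The networks are stiff: at high temperature the dimer pre-equilibrium
relaxes in milliseconds while a 0.5 °C/min ramp lasts hours. The compiled
core implements two adaptive Rosenbrock schemes over the temperature-
augmented state (temperature is a state variable with $\dot T$ equal to
the ramp rate, which makes the system autonomous within a program
segment):

* `rodas3` (default): a stiffly accurate, L-stable 4-stage order-3(2)
  pair. L-stability lets it stride over fast, fully relaxed
  pre-equilibria; it integrates the hardest default-design ramp in a few
  thousand steps.
* `kr4`: the classical Kaps–Rentrop order-4(3) method with Shampine's
  constants, A-stable but not L-stable; slower on stiff ramps but more
  accurate, used as the high-accuracy reference in the test suite
  (closed-form oracles are checked against it at `rtol = 1e-11`).

Because every Rosenbrock stage is a linear combination of $f$ and $J v$
terms, and strand mass is a *linear* first integral of mass-action
kinetics, the schemes conserve strand mass to rounding error regardless of
tolerance — the 1e-6 relative conservation requirement is met by
construction, and the test suite verifies it along every trajectory type.

Default tolerances are `rtol = 1e-7`, `atol = 1e-11` M for simulation and
`rtol = 1e-6`, `atol = 1e-10` M inside the fitting objective (an order of
magnitude below the 0.002 AU measurement noise in absorbance terms).
The absolute tolerance matters more than the relative one for speed: the
trimer passes through concentrations around $10^{-12}$ M at high
temperature, and controlling its *relative* error there is as expensive as
it is pointless. Halving both tolerances changes simulated absorbance by
well under $10^{-5}$ AU (tested).

Output is written on a uniform temperature grid (0.25 °C by default,
matching instrument-style sampling) by forcing integrator steps onto the
grid points; a dense-output interpolant would be marginally faster but the
step-forcing approach keeps the reported states exactly on-step.

## Initial-state protocols

A cooling trace starts from thermodynamic equilibrium at the upper span
temperature (at 85 °C effectively all monomer; the equilibrium solver
reduces the coupled equilibria to a strictly increasing quartic in the
free-monomer concentration, bisected and Newton-polished to machine
precision). A heating trace, by default, starts from the final state of a
simulated cooling ramp at the same rate — mimicking the anneal-then-melt
cycle of the real experiment. Alternatives (`equilibrium`, `all_monomer`
for an instantaneous snap-cool, or an explicit state) support the
rapid-anneal protocols. Isothermal courses default to `all_monomer`, the
idealised snap-cool.

## The synthetic world

The generator emulates the standard design: 50 and 250 uM strand, 0.5 and
5.0 °C/min, heating and cooling between 5 and 85 °C, 1 mm path length,
absorbance sampled every 0.25 °C, and additive iid Gaussian noise of
0.002 AU (a typical photometric noise floor; no temperature noise, no lamp
drift, no wavelength resolution — single effective wavelength only).

`default_truth()` is a *fixture of this package*, not fitted values from
any experiment (none are published for this system). Its values were
chosen once so that the trap world exhibits the documented qualitative
signatures — biphasic heating curves, pronounced hysteresis, trap
dominance after snap-cooling at 4 °C — and so that the benchmark is
well-posed:

* every step is partially rate-limiting somewhere in the design space, so
  all 16 kinetic parameters are locally identifiable from noiseless data
  (a fixture with a non-identifiable direction cannot serve as a recovery
  benchmark);
* the trap capture time (about a minute at 25 °C) is slow enough to keep
  both trap rate constants identifiable but fast enough to out-compete
  trimer formation at low temperature;
* the trap enthalpy is steep ($\Delta H_\mathrm{trap} = -35$ kcal/mol), so
  the apparent enthalpy of the low-temperature transition
  ($\Delta H_1 + \Delta H_\mathrm{trap} = -65$) is decoupled from the
  dimer stability that feeds tetramer assembly ($\Delta H_1 = -30$). This
  is the feature a bare sequential mechanism cannot mimic: forced to play
  the trap with its on-pathway dimer, it must distort that dimer's
  thermodynamics and starve its own assembly flux, which the
  multi-condition design exposes.

Equilibrium melting of the tetramer sits near 50 °C at 50 uM strand; the
trap melts kinetically near 33 °C on a 0.5 °C/min heating ramp.

What a green test does *not* establish: that real instrument data obey
additive white noise, that real baselines are linear, or that the
mechanism space contains only these two candidates. The generator is a
statistical twin of the published design, not of any particular
instrument.

## Fitting and model selection

`fit_global()` is a Levenberg–Marquardt least-squares solver with box
bounds (projected steps), forward-difference Jacobians on scaled
parameters, and seeded multi-start. TH objectives are multimodal; the
random multi-start is rarely decisive on its own, so `compare_models()`
implements the workflow that matters in practice:

1. fit the sequential mechanism;
2. fit the trap mechanism from a *family* of warm starts built on the
   model1 optimum: an almost-silent trap (guaranteeing in practice that
   the nested fit is never beaten by its special case), active traps
   spanning weak to steep trap enthalpies, and "de-mimicked" variants
   whose dimer step is reset to a generic fast-exchange dimer. The last
   group exists because a sequential fit to trap data absorbs the trap
   into its dimer step; descending from that optimum with every parameter
   free tends to stay in the mimicry basin.
3. compare by F-test, $F = \frac{(RSS_1-RSS_2)/df_1}{RSS_2/df_2}$ with
   $df_1 = p_2 - p_1 = 4$ and $df_2 = n - p_2$, p-value from the upper F
   tail. Baselines are shared between the two fits and counted in both
   $p_1$ and $p_2$, so the nesting is strict. If optimiser noise leaves
   the complex fit fractionally worse, F is clamped to zero with a warning
   rather than reported negative.

The decision threshold defaults to $p \le 10^{-2}$, the conventional level
for this comparison, and is configurable. Unweighted least squares with
shared baselines and no per-trace nuisance offsets is a declared choice
(an optional per-trace additive offset exists behind a flag in the
residual interface but is off by default: the experiment gives no license
for it).

Numerical notes: refitting from a returned optimum changes the RSS by at
most a few parts in $10^{4}$ (finite-difference Jacobian noise bounds the
achievable fixed-point sharpness — asserting bitwise RSS invariance under
refitting would be asserting something the arithmetic cannot deliver);
parameter-recovery tests therefore check the recovered parameters, not the
optimiser's trajectory. With noiseless data the fit recovers every
generating rate constant to better than 0.001 in log10 and every step
enthalpy to well under 2%.

## Known limitations

* Only the two published mechanisms are constructible; the network schema
  would admit others, but nothing else is validated, so `build_model()`
  refuses unknown names.
* The equilibrium solver requires every active step to be reversible — a
  state with an irreversible step has no finite equilibrium, and the
  hysteresis-against-equilibrium comparison is then undefined.
* The mid-transition (half-change) hysteresis width is only meaningful for
  traces whose transition completes within the span; for trap-world traces
  at 50 uM and 5 °C/min the annealing barely proceeds, and the apparent
  "width" of the composite biphasic curves is not monotone in scan rate.
  The scan-rate ordering property is therefore asserted in the regime
  where the measure applies (sequential world, 250 uM).
* At 5 °C/min the trap world's heating derivative shows a third, smaller
  feature between the trap and tetramer transitions (tetramer forming
  from freshly released strands during the ramp — visible in real
  experiments as scan-rate-dependent total absorbance change). The
  "exactly two maxima" biphasic signature is asserted on the 0.5 °C/min
  trace.
* CSV/JSON round trips are exact for the absorbance and parameter values
  (17 significant digits); trace *conditions* live in the manifest, not
  the CSV, so a trace file alone is not self-describing.
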