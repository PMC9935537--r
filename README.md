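# imotifTH

Kinetic analysis of thermal-hysteresis (TH) UV-melting experiments on
tetramolecular i-motif DNA.

## The problem

Four cytosine-rich strands assemble into a tetrameric i-motif through
dimeric and trimeric intermediates. Assembly is slow, so heating and
cooling absorbance traces separate (thermal hysteresis) and neither is an
equilibrium curve — but the dependence of that hysteresis on scan rate and
strand concentration encodes the assembly kinetics. Chemically modified
strands can additionally fold into a stable **off-pathway dimeric i-motif**
that acts as a kinetic trap and dramatically slows tetramer assembly.

`imotifTH` decides between the two candidate mechanisms from TH data:

* **model1** — sequential assembly: `M+M = D`, `D+M = Tri`, `Tri+M = T`;
* **model2** — the same pathway plus a unimolecular trap `D = Dstar`
  (strictly nested: silencing the trap step reproduces model1 exactly).

Every step is reversible with Arrhenius temperature dependence
`k(T) = k_ref * exp(-(Ea/R)(1/T - 1/T_ref))`; step enthalpies are
`dH = Ea_f - Ea_r`. Species populations map to 265 nm absorbance through
temperature-linear monomer/tetramer extinction baselines with folded-state
hypochromicity (intermediates interpolated between the endpoints). The two
mechanisms are fit globally to multi-condition trace sets by bounded
Levenberg–Marquardt least squares (baselines profiled out exactly at each
step) and compared by the nested-model F-test

```
F = ((RSS1 - RSS2)/df1) / (RSS2/df2),   df1 = p2 - p1 = 4,  df2 = n - p2,
```

with significance conventionally declared at `p <= 1e-2`.

The compiled core is a stiff-capable adaptive Rosenbrock integrator
(L-stable RODAS3 by default, Kaps–Rentrop 4(3) as a high-accuracy
reference) that conserves strand mass to rounding error by construction.
A synthetic-data generator reproduces the statistical structure of the
standard experiment (50/250 uM strand, 0.5/5 °C/min, 5–85 °C, 1 mm path,
0.002 AU Gaussian noise), so the whole pipeline is testable end to end.

## Worked example

```r
library(imotifTH)

# a synthetic trap-world dataset: 8 traces, sigma = 0.002 AU
design  <- experiment_design(noise_sigma = 0.002, grid_C = 1, seed = 4201)
dataset <- generate_dataset("model2", design = design)

# fit both mechanisms and compare
cmp <- compare_models(dataset, n_starts = 1, seed = 1, max_iter = 60)
cmp$ftest
#> F(4, 628) = 5.083, p = 0.00049 -> significant improvement at p <= 0.01
```

The F-test rejects the bare sequential mechanism: the residual improvement
from the trap step is far beyond what four extra parameters explain by
chance. On data generated *without* a trap the same pipeline reports no
improvement (`p` near 1).

Population dynamics behind the decision — a snap-cooled 50 uM sample held
at 4 °C:

```r
m2  <- build_model("model2", default_truth("model2")$steps)
iso <- isothermal_course(m2, T_C = 4, C_tot = 50e-6,
                         init = "all_monomer", duration = 86400)
tail(iso[, c("time_s", "frac_M", "frac_Dstar", "frac_T")], 1)
#>     time_s      frac_M frac_Dstar     frac_T
#> 400  86400 0.001677977  0.9562853 0.03009396
```

After 24 h the off-pathway dimer holds ~96% of the strands while the
tetramer — the thermodynamic ground state — has reached only ~3%: the
signature of a kinetic trap.

Simulated heating traces show the corresponding biphasic melting:

```r
ext  <- extinction_model(5.2e4, 60, 4.0e4, 30, dialect = "midpoint",
                         path_length = 0.1)
heat <- simulate_ramp(m2, "heating", rate = 0.5, C_tot = 50e-6, ext = ext)
dAdT_peaks(heat)
#>   temperature_C        dAdT
#> 1        32.875 0.001168356
#> 2        65.375 0.001972029
```

two melting transitions ~32 °C apart: the trap at low temperature, the
tetramer at high temperature.

A command-line interface covers the same pipeline
(`generate | simulate | isothermal | fit | compare`):

```sh
Rscript -e 'imotifTH::th_cli()' generate --model model2 --seed 7 --out data/
Rscript -e 'imotifTH::th_cli()' fit --model model1 --data data/ --seed 1 --out fit1.json
Rscript -e 'imotifTH::th_cli()' fit --model model2 --data data/ --seed 1 --out fit2.json
Rscript -e 'imotifTH::th_cli()' compare --fit1 fit1.json --fit2 fit2.json --out ftest.json
```

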