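# cntrelease

Analysis of drug release from carbon-nanotube carriers, in two arms:

* **Release kinetics.** Cumulative release time courses (e.g. doxorubicin
  released from modified multi-walled carbon nanotubes into buffer, measured
  by the UV-Vis standard-curve method) are fitted to seven classical
  dissolution models — zero order, first order, second order, Higuchi,
  Hixson–Crowell, Weibull, and the Korsmeyer–Peppas power law
  `C_t/C_inf = K t^n`. Models are ranked by the coefficient of determination
  R², and the transport mechanism is classified from the power-law exponent
  `n` (Fickian diffusion for n < 0.5, anomalous for 0.5 ≤ n < 1, Case II at
  n = 1, Super Case II above) or the Weibull shape `b` (Fickian for
  b ≤ 0.75, combined for 0.75 < b ≤ 1, complex above 1).
* **Configuration statistics.** For coordinate snapshots of a nanotube plus
  ligand molecules in a periodic orthorhombic box (XYZ or GRO input), the
  package computes single-linkage contact aggregates under the minimum-image
  convention, the percentage of molecules adsorbed by the tube, and the
  percentage encapsulated inside it via the ring / virtual-sphere counting
  algorithm.

A synthetic-data generator produces release curves and boxed nanotube/ligand
configurations with exact ground truth (free / aggregated / surface-adsorbed
/ encapsulated populations), which is how the package validates itself.
See the methods vignette (`vignettes/cntrelease-methods.Rmd`) for the models,
conventions and design decisions.

Intended users: formulation and nanomedicine researchers analysing
dissolution profiles, and simulation practitioners post-processing
nanotube–ligand configurations.

## Worked example

Simulate a six-point release curve from the power law (K = 0.7379,
n = 0.088, measurement noise sd 0.005), fit all seven models, and classify
the mechanism:

```r
library(cntrelease)
g <- generate_release_curve("power_law", c(K = 0.7379, n = 0.088),
                            noise_sd = 0.005, seed = 5)
fits <- fit_all(g$curve)
print(fits)
#> Kinetic model ranking (by R^2):
#>           model   r_squared converged n_params
#>       power_law   0.9962598      TRUE        2
#>         weibull   0.9791905      TRUE        4
#>      zero_order   0.8492331      TRUE        2
#>    second_order   0.8333975      TRUE        2
#>     first_order   0.5459975      TRUE        2
#>  hixson_crowell   0.5205407      TRUE        2
#>         higuchi -12.4316541      TRUE        1
mechanism_calls(fits)$power_law
#> Release mechanism: fickian (n = 0.0892206)
```

The power law wins the ranking (R² ≈ 0.996) and its fitted exponent
n ≈ 0.089 < 0.5 indicates Fickian (concentration-gradient-driven) release.

The configuration arm, on a generated study-geometry box (20 × 80 × 20 nm,
three-wall 6.42/7.12/7.83 nm tube, 100 ligand molecules of which 66 are
placed on the wall and 6 in the lumen):

```r
gen <- generate_configuration(n_free = 20, aggregate_sizes = c(5, 3),
                              n_surface = 66, n_inside = 6, seed = 5)
summarize_adsorption(gen$config, tube = gen$tube)
#> Adsorption summary: 23 aggregates (mean size 4.35), 72% adsorbed, 6% inside
```

72% of molecules sit in the nanotube-containing cluster and 6% are counted
inside the tube by the ring method — exactly the generator's intended truth
(66 + 6 adsorbed, 6 inside, out of 100).

File-based pipelines are available as `run_fit_kinetics()` (CSV in, JSON
report out) and `run_analyze_config()` (coordinate frames in, per-frame CSV
out), plus `simulate_release()` / `simulate_config()` writers.

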