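---
title: "Methods: release kinetics and nanotube adsorption statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: release kinetics and nanotube adsorption statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cntrelease)
```

# Scope

`cntrelease` supports two complementary ways of studying drug release from
carbon-nanotube (CNT) carriers such as doxorubicin (DOX) on multi-walled
nanotubes:

1. **Release kinetics**: fitting classical dissolution models to a cumulative
   release time course measured spectrophotometrically, selecting the best
   model by the coefficient of determination, and reading the transport
   mechanism off the fitted exponents.
2. **Configuration statistics**: given coordinate snapshots of a nanotube and
   ligand molecules in a periodic box (e.g. from a molecular-dynamics run),
   quantifying aggregation, the adsorbed fraction, and the fraction
   encapsulated inside the tube.

The package does not simulate dynamics; configurations are inputs. A
synthetic-data generator provides inputs with exact ground truth so that both
arms can be validated end to end.

# The kinetic models

Seven models are implemented, with $C_t$ the cumulative amount released by
time $t$ (minutes):

| Model | Form | Parameters |
|---|---|---|
| zero order | $C_t = C_0 + K_0 t$ | $C_0, K_0$ |
| first order | $C_t = C_d\,(1 - e^{-K_1 t})$ | $C_d, K_1$ |
| second order | $C_t = C_d - \dfrac{1}{1/C_d + K_2 t}$ | $C_d, K_2$ |
| Higuchi | $C_t = K_H \sqrt{t}$ | $K_H$ |
| Hixson–Crowell | $C_t = C_d - (C_d^{1/3} - K_{HC}\,t)^3$ | $C_d, K_{HC}$ |
| Weibull | $C_t = C_s\,(1 - e^{-(t-T)^b/a})$ | $C_s, T, a, b$ |
| power law (Korsmeyer–Peppas) | $C_t/C_\infty = K t^n$ | $K, n$ |

Conventions that the literature prints inconsistently are pinned down as
follows, each with an escape hatch:

* **Second-order sign.** The linear form is taken as
  $1/(C_d - C_t) = 1/C_d + K_2 t$ with $K_2 \ge 0$, so that release
  increases with time. The minus-sign variant occasionally seen in print
  (which makes release decrease) is available via
  `second_order_sign = "printed"`.
* **Weibull exponent grouping.** The default groups the scale parameter as
  $e^{-(t-T)^b/a}$, the classical dissolution Weibull in which $a$ sets the
  process timescale. The alternative grouping $e^{-((t-T)/a)^b}$ is available
  via `weibull_grouping = "scale_outside"`.
* **Zero-order intercept.** $C_0$ is a free parameter by default (release
  that starts from nothing usually has $C_0 = 0$; use `fix_c0_zero = TRUE`
  to pin it).
* **Hixson–Crowell** is clipped at complete dissolution $C_t = C_d$ once
  $C_d^{1/3} < K_{HC}t$.

The power law and Weibull describe the *fraction* of the equilibrium amount
released; curves recorded as raw amounts need `c_inf` ($C_\infty$) so they
can be rescaled.

## Fitting

The untransformed ("natural") scale is the default: nonlinear least squares
by Levenberg–Marquardt (`minpack.lm`), which treats every model on the same
footing and keeps $R^2$ comparable across models. A `"linearized"` option
reproduces classical practice (ordinary regression on $\ln(C_d - C_t)$ vs
$t$, $\log C$ vs $\log t$, and so on); its $R^2$ is then reported on the
transformed scale, which is not comparable with natural-scale $R^2$ — the
`fit_scale` field records which was used.

Starting values are deterministic and data-driven: log–log regression for
the power law, the $\sqrt t$ regression for Higuchi, the linearized
regressions for first/second order and Hixson–Crowell, and
$(C_s = \max C_t,\; T = 0,\; a = \mathrm{median}\,t,\; b = 1)$ for the
Weibull. No randomness enters the fit, so fits are exactly reproducible.

Two box constraints are physical rather than numerical: all rate constants
and shape parameters are non-negative, and the Weibull saturation level
$C_s$ — the total fraction eventually released — is capped at 1.05, the
same small-overshoot ceiling the fraction-scale data container allows for
noisy measurements. Without that cap the four-parameter Weibull can drift
into the regime $a \to \infty$, $C_s/a$ finite, where it degenerates into a
power law with $b \approx n$ while predicting a physically meaningless
eventual release far above 100%; capping $C_s$ keeps the model identifiable
and the comparison between models honest.

Model ranking uses $R^2 = 1 - SS_{res}/SS_{tot}$ in decreasing order.
Non-convergent fits are kept and flagged, ranked after every converged fit;
exact ties break toward fewer parameters, then lexicographic model name.
Degenerate data (all observations equal) make $SS_{tot} = 0$; $R^2$ is then
reported as `NA` rather than an arbitrary number.

## Mechanism classification

The power-law exponent $n$ maps to the transport mechanism as: Fickian
diffusion for $n < 0.5$; anomalous (diffusion plus swelling) transport for
$0.5 \le n < 1$; Case II relaxation-controlled transport at $n = 1$
(matched with absolute tolerance $10^{-9}$); Super Case II for $n > 1$.
The boundary $n = 0.5$ is assigned upward to the anomalous class because
the Fickian criterion is strictly "below 0.5". The Weibull shape $b$ maps
to: Fickian for $b \le 0.75$ (boundary inclusive), a combined mechanism for
$0.75 < b \le 1$, and a complex mechanism for $b > 1$. Both classifiers are
total and deterministic over their domains.

# Spectrophotometric accounting

The standard-curve method is a linear calibration of absorbance against
known concentrations; unknowns are inverted through the line, clipping
readings below the intercept to zero concentration with a warning.
Loading records carry explicit concentration units (`mg/mL` vs `ug/mL`)
because loading protocols routinely mix the two scales — e.g. a 40 mg/mL
loading solution dropping to 22.5 ug/mL after contact — and silent unit
mixing is the main foreseeable bug; all conversions are explicit. Percent
adsorbed is $100\,(1 - C_{final}/C_{initial})$ computed from the
concentrations as given. Percent released is
$100 \cdot m_{released}/m_{loaded}$ with
$m_{released} = C_{medium} \times V_{medium}$; sampling-volume depletion is
not modelled (no withdrawal–replacement correction), and a released mass
exceeding the load by more than 5% is treated as a calibration
inconsistency rather than silently truncated.

# Configuration statistics

## Aggregates

An aggregate is defined by single-linkage contact clustering: two molecules
(or a molecule and the nanotube) are linked iff any inter-atomic distance is
below the cutoff, with distances computed under the minimum-image convention
in the orthorhombic box. The default cutoff of 0.35 nm is a standard
heavy-atom contact criterion; it is configurable, and validity requires the
cutoff to stay below half the smallest box edge (checked). Single linkage is
transitive by construction, matching the physical picture of molecules held
in one aggregate by pairwise contacts. Cluster labels are deterministic
(numbered by lowest member index), so results are invariant under molecule
relabelling.

"Adsorbed by the nanotube" means membership in the nanotube-containing
cluster, so a molecule bound through a stack of other molecules counts as
adsorbed; a `direct_only` mode restricts to first-shell contact. Whether the
nanotube-containing cluster itself is included in the aggregate count is
controlled by `count_cnt_cluster` (included by default).

## Inside-the-tube counting (ring / virtual-sphere method)

The encapsulated fraction is computed by the per-ring algorithm: nanotube
atoms are partitioned into single carbon rings along the axis (axial bins of
0.213 nm, one zigzag ring-pair spacing, $\tfrac32 \times$ the 0.142 nm C–C
bond); each ring's centre of mass seeds a virtual sphere; a ligand molecule
is "inside" if its centre of mass falls in at least one sphere, counting
duplicates once. With ring spacing far below the sphere radius the union of
spheres is effectively a narrow capsule (finite cylinder with spherical
caps) coaxial with the tube, and for an ideal straight tube the result
equals exact capsule membership — a property the test suite checks by set
equality against an analytic oracle.

The sphere radius defaults to **half** the innermost wall diameter
(3.21 nm for a 6.42 nm tube): the lumen. Reports of this algorithm
sometimes state a sphere radius numerically equal to the tube *diameter*;
that convention would count molecules adsorbed on the outer wall as
"inside" and is geometrically inconsistent with encapsulation, but it is
available as `sphere_radius_mode = "printed"` for comparability.

Because the spheres ride on the actual ring centres, a bent or flexing tube
carries them with it, while a straight-cylinder approximation does not —
on flexible tubes the two counts disagree slightly, which is exactly the
small fluctuation this counter exhibits in practice. The generator can
produce sinusoidally bent tubes (`bend_amplitude`) and the suite asserts
the disagreement occurs.

# The synthetic generator

The generator emulates the geometry of the motivating study — a
$20 \times 80 \times 20$ nm periodic box; zigzag tubes of nominal diameters
6.42/7.12/7.83 nm (achieved diameter is the nearest realizable zigzag
diameter $d = 0.246\,m/\pi$, always within 0.04 nm), length 20 nm, axis
along $y$; the six-point sampling grid 1, 3, 5, 10, 20, 30 min — with four
controlled ligand populations: encapsulated (in contact with the inner
wall), surface-adsorbed (0.9 × cutoff from an outer-wall atom),
free-standing aggregates (chains of molecules with 0.8 × cutoff gaps), and
isolated free molecules. Ligands are rigid 3-bead chains (0.2 nm spacing,
unit masses): the statistics consume coordinates only, so chemical detail
would add nothing to the validation while obscuring the ground truth.

Placement margins make the intended answer the *unique* analysis result at
the generation cutoff: distinct entities are separated by more than
2 × cutoff, and every non-encapsulated molecule keeps its centre of mass at
least 0.5 nm clear of the ring-method capsule so that no molecule sits in
the ambiguous shell at the sphere boundary. Release curves get additive
homoscedastic Gaussian noise (clipped at zero), with a proportional-noise
option; noiseless curves reproduce their model exactly, which is the basis
of the round-trip tests. All generators are deterministic per seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: aggregation kinetics (the decay of the aggregate
count over nanoseconds), force-field energetics, realistic all-atom DOX
geometry, thermal wall flexing beyond the parametric sinusoidal bend, and
heteroscedastic assay error unless requested. Closure tests certify the
*statistics*, not any dynamical claim.

# Numerical choices and problem sizes

* Levenberg–Marquardt runs with `maxiter = 1000` and
  `ftol = ptol = 1e-15`, tight enough that noiseless round trips recover
  parameters to better than $10^{-6}$ relative.
* $R^2$ is undefined (NA) for degenerate data; non-convergence is reported,
  never silently dropped.
* Classification boundaries: $n = 0.5 \to$ anomalous, $b = 0.75 \to$
  Fickian, $n = 1$ within $10^{-9}$ absolute $\to$ Case II.
* Validation sizes: parameter recovery uses 200 six-point curves with noise
  sd 0.01 on the fraction scale ($n$ uniform on $[0.05, 0.95]$, $K$ on
  $[0.2, 0.9]$); model selection uses 100 curves at $n = 0.1$; clustering
  is checked against a brute-force $O(N^2)$ union-find oracle on 100 random
  periodic configurations; closure uses 50 generated boxes mixing
  single-wall and full three-wall geometries. These sizes give stable
  statistics while keeping the whole suite fast on a single CPU.

# Known limitations

* The linearized fits that need a saturation amount fix it at $C_\infty$
  when supplied and at $1.05 \times \max C_t$ otherwise; for strongly
  incomplete release this inflates the fixed $C_d$ and the linearized $K$
  estimates accordingly. The natural-scale fit has no such issue.
* The ring method's capsule equivalence holds exactly only for ideal
  straight tubes; on bent tubes the deviation is the documented feature.
* Single-frame analysis only: multi-frame trajectories are handled as lists
  of files, not trajectory formats.
* The clustering is $O(N_{atoms}^2)$ in memory for the molecule–molecule
  distance matrix; it is sized for analysis snapshots (thousands of atoms),
  not production MD systems.
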