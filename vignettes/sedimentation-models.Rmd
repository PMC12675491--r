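---
title: "Predicting macrophyte sedimentation velocity: models, fitting and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting macrophyte sedimentation velocity: models, fitting and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkvel)
```

## The problem and the model chain

A negatively buoyant particle released in still water accelerates until drag
balances its effective weight and then settles at a constant terminal
velocity ω. For a sphere of diameter *d* that balance gives

$$\omega = \sqrt{\tfrac{4}{3}\,\frac{(\rho/\rho_{sw} - 1)\, g\, d}{C_D}},$$

with particle density ρ, water density ρ~sw~, gravitational acceleration *g*
and drag coefficient *C~D~*. Exact drag solutions exist only for spheres and
spheroids in laminar flow; drifting macrophytes — blades, filaments, tangled
branched thalli — generate surface turbulence no analytical drag theory
covers. The package therefore implements an empirical chain built on two
shape-blind-to-shape-aware descriptors:

* the **nominal diameter** `nominal_diameter()`,
  $d_n = 2\,(3V/4\pi)^{1/3}$, the diameter of the volume-equivalent sphere —
  it depends only on volume, never on shape;
* the **Corey shape factor** `corey_shape_factor()`,
  $S_f = c/\sqrt{ab}$ over the longest, intermediate and shortest mutually
  perpendicular axes — scale-free (invariant under uniform rescaling), 1 for
  a sphere, and far below 1 for thin blades.

Treating the particle as an ellipsoid inserts $S_f^{2/3}$ into the numerator
of the balance, and the drag is closed empirically as

$$C_D = \Big(\frac{X_2\,\nu}{d_n^{1.5} g^{0.5}} + X_3\Big)^{X_1},$$

where $\nu/(d_n^{1.5} g^{0.5})$ is a dimensionless laminar group, $X_2$
describes the laminar and $X_3$ the turbulent behaviour, and both may depend
on $S_f$. Three fitted structures are shipped as presets of `model_spec()`:

* **Model A** (one constant, no shape dependence):
  $C_D = k\,\nu/(d_n\,g)$ with $k = 4\,567\,661$. Note this drag group is
  *not* dimensionless; the constant absorbs units, which is why every model
  evaluation in this package demands SI inputs.
* **Model B** (one constant, shape in the numerator only):
  $C_D = k\,\nu/(d_n^{1.5} g^{0.5})$ with $k = 4\,146.337$.
* **Model C** (eight constants, shape in numerator and drag):
  $C_D = \big((k_{lam0} + k_{lam1} S_f)\,\nu/(d_n^{1.5} g^{0.5}) + k_{turb0}
  - k_{turb1} S_f^{p_{turb1}} - k_{turb2} S_f^{p_{turb2}}\big)^{p_{outer}}$.

Model C is the most accurate structure for macrophytes, but its drag base
turns negative once $S_f$ grows past roughly 0.03–0.25 (the boundary moves
with $d_n$ and ν). The package treats that as a *refusal*, not a number:
`predict_velocity()` flags the row (`in_domain = FALSE`, `NA` velocity, a
diagnostic string) or raises a classed error under `on_invalid = "error"`.
Sphere-like objects (table-tennis balls, rubber bands, $S_f \to 1$) are
always refused by structure C at macrophyte scales; structure B remains
finite there and is the recommended generalist. Buoyant particles
(ρ ≤ ρ~sw~) get a *buoyancy* error class distinct from domain errors, since
settling velocity is undefined for them rather than out of range.

## Trait derivation routes

The three model inputs per specimen are volume, wet weight and shape.
Density is the ratio of blotted wet weight to displacement volume
(`mass_density()`); repeated volume/weight measurements are averaged, with a
warning when replicates diverge by more than 5% of their mean — mirroring
the bench protocol of re-measuring on divergence without discarding data.

Shape is the awkward one: tangled thalli do not expose three measurable
axes. `derive_traits()` routes each specimen by its `morphology` column:

* `flattened` — the scanned projection area is the product of the two
  longest axes, $P = ab$, and thickness follows from volume, $c = V/P$, so
  $S_f = V\,P^{-3/2}$ (`shape_factor_flattened()`);
* `cylindrical_or_branched` — the mean width of the youngest branches is a
  direct measure of $c$, and $ab = V/c$, so $S_f = c^{3/2}/\sqrt{V}$
  (`shape_factor_branched()`);
* `direct_axes` — plastics and other rigid objects with measurable axes use
  the definition directly.

For any box-like particle with $V = abc$ the three routes agree to machine
precision (a property test enforces this), and a derived $S_f > 1$ is
rejected as a morphology misclassification rather than clamped.

## Water properties

No seawater-properties package is assumed; the two standard correlations are
implemented internally. Density uses the one-atmosphere EOS-80 equation of
state (valid 0–40 °C, 0–42 practical salinity); kinematic viscosity divides
the Sharqawy-type dynamic-viscosity correlation (IAPWS-based pure-water term
with a quadratic salinity correction) by that density. At 20 °C fresh water
this yields ν within 1% of the handbook value 1.004·10⁻⁶ m² s⁻¹, and at the
brackish study conditions (≈15 psu, 17–18 °C) it lands within 0.5% of the
deposited median 1.0915·10⁻⁶ m² s⁻¹. Because no correlation is exact,
`medium_override()` lets known conditions — e.g. the study's median medium,
exposed as `median_study_medium()` — be injected verbatim. Monotonicity
(density rising with salinity, viscosity falling with temperature) is
verified on a grid across the validity box.

## Refitting constants: the genetic algorithm

`fit_model()` minimises the mean squared error between predicted and
observed velocities over the free constants of one structure, using a
real-coded genetic algorithm. The defaults in `ga_config()` are the
study-scale settings: population 5000, crossover probability 0.8, mutation
probability 0.1, elitism 250, at most 500 000 generations, stopping when the
best objective has not improved for 5000 generations. The published
hyperparameters do not pin down the encoding or operators, so those are this
package's own design:

* **Encoding.** Multiplicative constants are searched as log₁₀ values;
  the fitted presets span 0.89 to 4.6·10⁶, so a linear encoding cannot move
  across the space. Exponents ($p_{turb1}$, $p_{turb2}$, $p_{outer}$) are
  searched linearly. Default bounds are three decades either side of the
  preset for multiplicative constants and [0, 100] for exponents, fully
  overridable per constant.
* **Operators.** Tournament selection (size 3), BLX-α blend crossover
  (α = 0.5) and per-gene Gaussian mutation (σ = 10% of the gene's bound
  width), clamped to the box. Elitism guarantees the recorded best-objective
  history is non-increasing, which a test asserts.
* **Domain penalty.** Structure-C candidates frequently push some
  observation outside the drag base's validity. Such candidates receive a
  large finite penalty — 10³ times the worst in-domain squared error in the
  current population — *plus* the summed magnitude of the base violation, so
  even an all-infeasible population retains a selection gradient back toward
  the feasible region.
* **Local polish.** After the GA stops, a bounded quasi-Newton refinement
  (Nelder–Mead pre-stage, then L-BFGS-B) is started from the best
  individuals and kept only if it improves the objective. The study-scale GA
  buys its final precision with hundreds of thousands of generations; the
  polish recovers that precision at desk scale. It can be disabled
  (`local_polish = FALSE`) to study the raw GA.

Reproducibility is exact: the same seed, configuration and data give an
identical `sinkvel_fit`, and the fit restores the caller's RNG state. On
noiseless synthetic data the one-constant structures A and B are recovered
essentially to machine precision; for the eight-constant structure C the
surface is partially degenerate (several constants — notably $p_{turb2}$ —
are unidentifiable from macrophyte-range shape factors, where
$S_f^{52}$ is numerically zero), so *predictive* agreement on held-out data,
not constant-wise identity, is the recovery criterion.

## Evaluation metrics

The headline accuracy metric is the **median squared deviation**
(`median_squared_deviation()`): the median of squared observed-minus-
predicted velocities, in m² s⁻², read literally as median-of-squares (even
lengths average the two central order statistics). The GA optimises the
*mean* squared error, so `evaluate_predictions()` reports both, alongside
the r² of the ordinary least-squares observed~predicted line
(`observed_predicted_r2()`). Replicate velocities are collapsed per specimen
by `aggregate_replicates()` — mean with range by default (the convention
used when fitting), or median with type-7 quartiles. The quartile convention
is recorded in the CLI report output. `split_modeling_testing()` partitions
specimens into the fitting and validation groups and refuses overlapping or
unknown labels. `reproduce_study_metrics()` chains all of this over the
three preset models for user-supplied trait/observation/split files — the
opt-in path for re-deriving dataset-level metric tables when a full measured
dataset is locally available; the default test suite exercises the wiring on
synthetic stand-ins only.

## What the synthetic generator emulates — and what it does not

`generate_specimens()` draws nominal diameters log-uniformly over
0.576–4.844 cm and shape factors log-uniformly over 0.00029–0.0689, the
spans observed across the study's macrophytes; both quantities range over
roughly two decades, which motivates the log-uniform choice. Densities are
lognormal around the deposited median 1104.44 kg m⁻³ with sdlog 0.04 — the
published table reports the median but not the spread, and 0.04 (≈ ±12% over
3σ) brackets the densities implied by the printed weight and volume ranges.
The default medium is the median experimental one (ρ~sw~ = 1009.45 kg m⁻³,
ν = 1.0915·10⁻⁶ m² s⁻¹).

Two couplings make the draws faithful rather than merely in-range:

* **Buoyancy–shape coupling.** In the measured data no negatively buoyant
  seaweed had $S_f > 0.0278$; the compact, often vesicle-bearing thalli with
  larger shape factors floated. The generator reproduces this: macrophyte
  draws above `s_f_sink_max = 0.0278` are emitted as floating specimens
  (density just below the water's), which also keeps the generating model
  away from its near-singular domain boundary where drag tends to zero and
  velocities would be physically absurd. Plastic mode disables the coupling
  (dense plastic spheres genuinely sink).
* **Route consistency.** Each specimen carries measurement columns
  (projection area, branch width, or direct axes) constructed to reproduce
  the drawn shape factor exactly through the corresponding derivation route,
  so reader → deriver → model pipelines can be tested end to end.

`generate_observations()` evaluates the generating model per sinking
specimen and multiplies by lognormal noise with mean exactly 1 and the
configured coefficient of variation (default 0.1, five replicates) —
multiplicative because replicate spread scales with velocity and positivity
must be preserved. Floating specimens are emitted with a buoyancy flag and
no velocity. Draws the generating model refuses are redrawn, at most 100
times per specimen, then the generator errors rather than silently distort
the distribution.

The generator deliberately does **not** emulate: species identities or
taxonomic contrasts, the correlation structure between size, shape and
density across real specimens (independence is assumed), batch structure
across sampling campaigns, thallus flexibility or reconfiguration under
flow, and surface-material effects on drag. Passing tests on synthetic data
therefore demonstrate that the chain is self-consistent and that the
optimiser recovers known generating processes — not that the models
extrapolate to taxa or shapes outside the measured trait ranges.

## Numerical choices

* Shape-factor powers are evaluated as $\exp(p \log S_f)$; the
  $S_f^{52.04557}$ term underflows harmlessly to zero across the macrophyte
  range (it is below 10⁻¹⁵ for all $S_f \le 0.5$), which is numerically
  exact behaviour, not error.
* Velocities are computed in plain arithmetic; a separately coded
  log-domain evaluator (every product a sum of logs) serves as the test
  oracle, with agreement required to 10⁻¹⁰ relative on 1000 random
  in-domain inputs.
* Neutral buoyancy (ρ = ρ~sw~) yields ω = 0 exactly in all structures, and
  the buoyancy classifier calls an exact tie *floating* with a flag.
* Surface grids (`prediction_surface()`) mask invalid cells per cell rather
  than failing the grid.
* Table round-trips preserve numeric fields to at least 12 significant
  digits; unit conversion happens once, at the file boundary, via explicit
  `*_unit` columns.

## Desk-scale test sizes

The shipped tests run the optimiser at reduced scale — populations of
40–400, stall windows of 30–300 and a few thousand generations — which the
polish stage makes sufficient: structure B recovers its constant to ~10⁻¹⁶
relative at population 80, and the structure-C predictive-recovery check
(40 noisy training specimens, 40 held-out) agrees with the generating model
to well under 2% RMS in seconds. The full-scale defaults remain available
for real refits where run time is not a constraint.

## Known limitations

* **Model C is not globally monotone in shape factor.** Within its valid
  domain, ω always rises with $d_n$ at fixed $S_f$, but at the small end of
  the study's size span (d_n ≲ 0.8 cm) ω *dips* by up to ~2% as $S_f$ grows
  through ≈0.006–0.01: the laminar drag term $(k_{lam0}+k_{lam1}S_f)$ grows
  fast enough at small diameters that $C_D^{5.57}$ briefly outruns the
  numerator's $S_f^{2/3}$. The broad picture — large macrophytes with small
  shape factors sink far more slowly — holds; the fine-grained surface is
  not monotone everywhere, and the surface-monotonicity test records this
  honestly.
* Model C refuses high-shape-factor particles by construction; use model B
  for spheres, bands and other compact objects.
* The constants are empirical and SI-bound; there is no mechanism for unit
  inference inside the models, and no uncertainty quantification of the
  constants is provided (none exists for the presets either).
* Only still-water terminal settling is modelled: no acceleration phase, no
  horizontal drift or currents, no flexible-thallus reconfiguration, no
  pressure dependence of water properties.
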