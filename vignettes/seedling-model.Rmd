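---
title: "A functional–structural model of maize seedling nutrient acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A functional–structural model of maize seedling nutrient acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rhizoseed` simulates single maize or teosinte seedlings over their first
25 days to ask two questions: how much do seminal roots contribute to
nitrogen and phosphorus acquisition, and how do seed carbohydrate reserves
constrain the seminal root number that maximizes growth? This vignette
describes the model, its assumptions, the parameters that matter, how the
synthetic fixtures were built and calibrated, and what the package's tests
do and do not establish.

## The coupled model

A simulation couples a root architecture model, a plant carbon budget and
a one-dimensional soil column at a time step of 0.25 d (`sim_control()$dt`).
Each step runs, in order: soil water and nitrate transport and
mineralization; nutrient uptake; stress-factor update; photosynthesis and
seed-reserve draw; carbon allocation; root elongation and branching.

### Root architecture

Roots are chains of cylindrical segments no longer than 1 cm, tagged by
class: primary, seminal, nodal (crown), and a first-order lateral class
for each axial class. Each class carries an emergence day, an insertion
angle (degrees from vertical, or from the parent axis for laterals), a
linear-in-age elongation rate (the first derivative of a quadratic fit to
serial harvest data; `fit_growth_rate()`), a diameter, a tissue density
and a maintenance respiration rate. Branching frequencies are drawn
uniformly from a per-class range at every branching event, reproducing the
observed variability; the apical 2 cm of an axis never branches (a
standard value — the studies this model emulates do not report one).
Trajectories combine a per-segment Gaussian deflection (component sd 0.09,
about 5°) with a class-specific gravitropic pull, strongest for the
primary root; the insertion angles are parameters, the tortuosity model is
ours. Roots reflect at the vertical prism walls — mirror symmetry standing
in for the roots of neighbouring plants — and are deflected to horizontal
at the bottom. Laterals are first order only: second-order laterals are
never parameterized in the seedling data this model follows, and at 25 d
they would contribute little length.

A numerical note: growth shorter than `emit_min` (0.5 cm) is buffered per
tip and emitted as a segment once accumulated, so the segment count tracks
root length rather than the number of time steps; buffered growth is
flushed at the end of a run. Construction carbon is charged when the
growth happens, not when the segment is written.

### Carbon economy

The seed holds `seed_mass × carbohydrate_fraction` mg of carbohydrate,
convertible to carbon at 0.42 g C per g. Reserves are supplied **on
demand**: each step the plant's sinks (mesocotyl before emergence, roots,
stem, leaves, maintenance respiration) are summed and any shortfall after
photosynthate is drawn from the reserve. The mesocotyl is an explicit
sink; the seedling emerges when its length reaches the planting depth, and
a seedling whose reserve runs out before it has ever produced
photosynthate is flagged as a germination failure and stops growing — this
is the mechanism behind the small-seed, high-seminal-root failures. Leaf
area expands only after emergence at a stress-scaled linear-in-age rate;
photosynthesis is `lue × PAR × (1 − exp(−k·LAI))` over the plant's ground
area (PAR 600 µmol m⁻² s⁻¹ for 14 h, the growth-chamber regime used for
parameterization; light-use efficiency 0.5 g C mol⁻¹ and extinction 0.6).
Carbon is partitioned among roots, stem and leaves by allocation
coefficients (0.35/0.25/0.40) with a waterfall: a sink never receives more
than its demand and declined carbon is re-offered to unsatisfied sinks.
Construction carries a growth-respiration overhead of 1.3; structural
tissue is 0.45 g C per g dry weight, and shoot dry weight is shoot
structural carbon divided by that fraction.

### Soil column

Each plant owns a column of 1-cm layers spanning its ground area (prism
width × length). Water follows a tipping bucket: infiltration fills layers
to field capacity top-down, the excess cascades and leaves the bottom as
drainage, and evaporation (2 mm d⁻¹) dries the top layers to wilting
point. Nitrate moves with the water by conservative upwind convection plus
hydrodynamic dispersion (`dispersivity × |flux|`), sub-stepped when the
advective Courant number exceeds 0.5; mass balance is exact by
construction. Organic-matter nitrogen mineralizes into nitrate at
`k0 (t+1)^(−s)` (defaults 0.012 d⁻¹, s = 0.5) — a declining-rate aging law
standing for the progressive recalcitrance of the remaining pool.
Ammonium is not modelled (nitrification is fast in the fields being
emulated).

Nitrate uptake per unit root surface follows Michaelis–Menten kinetics in
the layer's solution concentration, rationed so a layer never yields more
than it holds and the plant never takes more than its current deficit.
The default kinetics (i_max 12 µmol cm⁻² d⁻¹, K_m 30 µmol cm⁻³) are an
*effective* parameterization: the high K_m stands for the transport
limitation between bulk soil and root surface that a 3-D solute model
would resolve, and it is what makes nitrate availability (rather than
surface area alone) limiting at 50 kg ha⁻¹.

Phosphorus uptake uses the Barber–Cushman radial model: around each root,
`b ∂C/∂t = (1/r) ∂/∂r (r De b ∂C/∂r + r v0 r0 C)` on `r0 ≤ r ≤ rx` with
Michaelis–Menten influx at the root surface and zero flux at the
half-distance boundary `rx` (0.6 cm). The solver (compiled, implicit in
diffusion with the influx linearized into a Robin boundary term) keeps one
depletion state per root class × soil layer × day-of-arrival cohort and
apportions uptake by root length — equivalent to per-segment solving when
cohort members share parameters, at a small fraction of the cost. Layer
labile-P pools are authoritative: cohort uptake is rationed against them,
so the phosphorus balance closes exactly.

### Nutrient stress

The plant's optimal N and P contents are tissue masses times optimal
tissue concentrations (defaults: root 1200/45, shoot 2000/55 µmol g⁻¹ for
N/P). The stress factor is `max(floor, actual/optimal)` capped at 1, with
floor 0.1 — the simplest monotone response; the binding (minimum) of the N
and P factors multiplies leaf expansion, photosynthesis and root
elongation. Liebig-style minimum rather than multiplicative combination is
the common default in this model family.

## Synthetic fixtures and calibration

No measured parameter tables, weather records or soil profiles ship with
the package; `make_phenotype_fixture()`, `make_environment_fixture()` and
`make_composite_fixtures()` generate documented stand-ins, and every
numeric default carries a provenance label in the fixture manifest:

* **printed-in-paper** — the anchors: landrace seed mass 280 mg with
  carbohydrate fraction 0.7112, teosinte seed mass 30 mg and typically no
  seminal roots, nodal roots emerging 7 d after planting, the
  60 × 26 × 150 cm prism, 76.2 cm row spacing, 50 kg ha⁻¹ available
  nitrate and 2 kg ha⁻¹ available phosphorus as the low-nutrient
  conditions.
* **derived-from-paper** — the teosinte carbohydrate fraction
  0.7112 / 1.34 ≈ 0.531, from the landrace value and the reported 34 %
  carbohydrate excess of landrace over teosinte kernels.
* **literature-default** — diameters, angles, tissue density, respiration,
  soil hydraulics for the silt loam and sand.
* **free-calibration** — everything the sources do not pin down: seed N
  and P, optimal tissue concentrations, elongation and leaf-expansion
  rates, uptake kinetics, the teosinte mesocotyl rate, the nitrate
  e-folding depth (20 cm) and the rainfall season.

"Available" nutrients are operationalized as column integrals: the nitrate
profile (exponential, surface-concentrated) is scaled so the 150-cm column
holds the stated kg ha⁻¹; labile P likewise via the buffer power. The
organic-N pool defaults to the nitrate target and sits in the top 30 cm.

The rainfall fixture is a deterministic **design season**: nine wet days
grouped into storms, depths from exponential quantiles (mean 10 mm),
rescaled to the expected 90 mm over 30 days. A single fixed season mirrors
the study design, in which every treatment shared one measured record and
replicate variation came from the plant, not the weather; a drawn-at-random
season would make the stressed/unstressed contrast depend strongly on the
luck of the storms (`make_rainfall_series(stochastic = TRUE)` exists for
weather studies).

The free-calibration values were tuned, once, against the printed study
outcomes: seminal roots plus their laterals contributing ~35 % of 25-day N
and P uptake; the 50 kg ha⁻¹ N and 2 kg ha⁻¹ P environments each halving
day-25 shoot dry weight; teosinte failing to germinate when forming two or
more seminal roots; and seminal roots ceasing to pay off below roughly
45 mg of seed carbohydrate. The calibrated model reproduces these
quantities within the tolerances asserted in `test-acceptance.R`; they are
emergent (nothing in the code stores the target numbers).

The low-N environment is generated with non-limiting phosphorus
(100 kg ha⁻¹) and the low-P environment with non-limiting nitrogen
(400 kg ha⁻¹), so each stress is attributable; the non-limiting control
scales both far beyond demand (stress factors stay at 1 throughout).

## The experiments

`run_simulation()` returns per-day budgets, cumulative uptake arrays at
root-class × layer × day resolution (what `class_contribution()` and
`by_depth_contribution()` consume; laterals are their own stratum so the
seminal-plus-laterals share is separable), the final geometry and exact
mass-balance bookkeeping. `run_env_grid()`, `run_density_sweep()` (which
also computes nearest-neighbour root distance CDFs between a plant and its
in-row neighbour, from segment midpoints, under nutrient multipliers high
enough to avoid allometric confounding) and `run_srn_sweep()` run seeded
replicate factorials; replicate seeds are `base + cell × 1000 + replicate`
and are recorded per row. Following the study's practice, sweeps report
replicate values and means of at least six seeded replicates and no
hypothesis tests.

`optimize_srn()` runs seminal root numbers 0–8 against seed masses
10–150 mg (2.5-mg steps, 20 replicates by default) with the carbohydrate
fraction held at 0.7112 and seed N and P fixed at the base phenotype's
values. `select_optimum()` rounds mean shoot dry weight to six decimal
places and takes the smallest seminal root number attaining the maximum,
so sub-microgram differences never justify an extra root. The acceptance
computations coarsen the grid to 5-mg steps and 5 replicates — 2 × 2 610
runs — purely to keep a desk-scale runtime; `reserve_threshold()` converts
the optimum table to the smallest carbohydrate reserve favouring seminal
roots, and the reported threshold is the smaller of the low-N and low-P
values (below it the optimum is zero in both environments).

## Numerical choices

* Coupling step 0.25 d; nitrate transport sub-steps at Courant 0.5;
  the radial P solver uses 14 log-spaced nodes and 2 sub-steps per
  coupling step (validated to 2 % against a 10×-refined explicit
  oracle in the test suite).
* The Michaelis–Menten influx boundary is linearized about the current
  surface concentration and solved implicitly with the diffusion operator;
  an operator-split explicit influx capped by the first-cell content
  systematically starves uptake on fine grids and was rejected.
* All pools are clamped non-negative through proportional rationing, never
  truncation, so every balance (water, N, P, carbon) closes to round-off
  and is asserted in tests.
* Depth bins are half-open `[k, k+1)` cm; z is positive downward with the
  origin at the soil surface over the seed.
* Ties in `select_optimum()` resolve to the smallest seminal root number;
  rounding is applied to cell means in grams at six decimals.

## Limitations

The model is deliberately a desk-scale emulation, not a reimplementation
of a 3-D finite-element platform. Water flow is a tipping bucket, not
Richards flow; solutes move vertically only, so horizontal structure
enters purely through root geometry and per-layer rationing. Nitrate
kinetics are effective, not mechanistic. There is no root thickening,
cortical aerenchyma, tillering, soil temperature or hardness response, and
no drought physiology. The synthetic fixtures reproduce the printed
contrasts between the two genotypes but are not the measured parameter
tables; passing tests demonstrate that the model family with the
documented calibration reproduces the study's qualitative and headline
quantitative behaviour, not that the fixture values equal the measured
ones. Conclusions about real germplasm should rest on measured parameters
fed through the same machinery via the config interface
(`write_phenotype_config()` / `read_phenotype_config()`).
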