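---
title: "From incubation kinetics to a global carbon-preservation flux"
author: "maillard package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From incubation kinetics to a global carbon-preservation flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maillard)
```

## The scientific problem

Reducing sugars and amino acids in marine sediment pore waters can
polymerize abiotically (the Maillard reaction) into geopolymerized
substances (GPS): aromatic macromolecules above the operational
1,000 g mol⁻¹ dialysis cutoff that microbes cannot readily ingest or
hydrolyse. Dissolved Fe and Mn, and especially their mineral forms
(ferrihydrite, birnessite), catalyse this reaction by up to two orders
of magnitude at the ~10 °C typical of continental-margin sediments.
This package estimates how much organic carbon such catalysed
geopolymerization could preserve globally, and propagates the
uncertainty of every laboratory-derived parameter to that estimate.

The chain has five stages, each usable on its own.

## 1. Kinetics: rates from incubation series

GPS concentration grows linearly with time over the incubation window,
so the production rate is the OLS slope of GPS (nmol l⁻¹) on elapsed
time (years). Assumptions and choices:

* **Pooled replicates.** The default regression pools all replicate
  observations; standard errors then reflect both within- and
  between-replicate scatter. A `per_replicate` mode fits each bottle
  separately for diagnostics, but the pooled slope remains the contract
  rate.
* **Free intercept.** The intercept (initial background GPS) is
  estimated, never forced through zero: forcing would bias the slope
  whenever the t = 0 sample contains any pre-formed polymer.
* **Units.** Time is stored in years internally; `time_days` columns
  are converted on read (÷ 365.25). Rates convert to the upscaling unit
  mol m⁻³ yr⁻¹ by the exact factor 10⁻⁶.
* **Degenerate inputs.** Fewer than two distinct time points is a
  degenerate design and errors; exactly collinear data legitimately
  return `stderr = 0`, `r_squared = 1`.

## 2. Particle physics: Stokes–Einstein molecular weight

Dynamic light scattering gives the GPS hydrodynamic radius
(3.25–4.36 nm, peak 3.77 nm, measured at 25 °C). The diffusion
coefficient is $D = k_B T / (6\pi\eta r_h)$ and the molecular weight

$$\mathrm{MW} = \frac{R^3 T^3 \rho}{162\,\pi^2 N^2 \eta^3 D^3},$$

with $\rho$ = 1,500 kg m⁻³ (the standard biomolecule density) and
$\eta$ the water viscosity. Substituting $D$ shows the temperature and
viscosity cancel: the chain collapses to the sphere mass
$\tfrac{4}{3}\pi r_h^3 \rho N_A$. Two numerical consequences were
designed in:

* The gas constant is stored as the exact product $k_B N_A$
  (≈ 8.3145 J K⁻¹ mol⁻¹), so the cancellation holds to machine
  precision instead of being limited by a rounded constant. The
  equivalent closed form `mw_from_radius()` is exposed and used when
  building sampling ranges directly from radii.
* Because of the cancellation, MW is insensitive to whether the DLS
  temperature (298.15 K) or the incubation temperature (283.15 K) is
  used, provided $D$ and MW use the same pair. We fix 298.15 K and
  η = 8.90 × 10⁻⁴ Pa s (water at 25 °C), matching the measurement
  conditions, and expose both as arguments.
* The carbon mass fraction of GPS defaults to **0.40** — a placeholder
  on the plausible range for melanoidin-like material, to be overridden
  with an elemental-analysis value; it is a first-class argument and a
  Monte Carlo range precisely because it is uncertain.

All molecular weights generated from the measured radius range exceed
the 1,000 g mol⁻¹ cutoff by two orders of magnitude, so the estimator
never counts material the dialysis step would have discarded.

## 3. The margin grid and oxygen penetration depth

Preservation is assumed to occur in the oxic surface layer of
continental-margin sediments (water depth 0–1,000 m: shelf plus upper
slope). Each cell of a regular lat–lon grid carries depth, porosity,
bottom-water temperature and spherical-Earth area, from which the oxic
pore-water volume is $\mathrm{PV} = \varphi \, Z_{O2} \, S$.

* **OPD law.** The oxygen penetration depth follows a log–log linear
  law in water depth, $\log_{10}(Z_{O2}/\mathrm{cm}) = a + b
  \log_{10}(d/\mathrm{m})$. The published analyses report only the
  resulting envelope (0.56–1.10 cm, mean 0.66, SD 0.13), not the
  coefficients, so the default relation is the exact two-anchor
  calibration through (10 m, 0.56 cm) and (1,000 m, 1.10 cm);
  `calibrate_opd()` accepts any anchor set.
* **Depth floor and clamp.** Depths below 10 m are floored before the
  log (the power law is not calibrated nearshore), and the evaluated
  OPD is clamped to the calibrated envelope so synthetic bathymetry
  cannot extrapolate outside it. Both are arguments; clamping can be
  disabled.
* **Compaction ignored.** Porosity is depth-constant within the OPD by
  contract: compaction matters over tens of metres, not the top
  centimetre.
* **Registration.** Cell centres with half-open [south, north) ×
  [west, east) bounds avoid double counting at seams; summed cell areas
  reproduce closed-form band areas to 10⁻¹⁰ relative.
* **Masking.** Land (depth ≤ 0), deep-sea (depth > 1,000 m) and
  non-finite cells are inactive and contribute nothing to any total.

Grids are serialized as plain-text CSV with a `#key: value` attribute
header (units, registration, shape) — self-describing, diff-able, and
the interchange point for real gridded datasets.

## 4. Upscaling

Laboratory rates transfer to each cell by the Arrhenius equation using
the cell's bottom-water temperature (the standard proxy for surface
sediment temperature), with $T_{Lab} = 283.15$ K; the per-cell flux is
$C_{pres} = \mathrm{MW}\cdot C_{cont}\cdot \mathrm{PV}\cdot R$ in
g C yr⁻¹ and the global total is reported in Tg C yr⁻¹. Only
mineral-catalysed rates are admitted to upscaling by default — dissolved
Fe/Mn and control fits require an explicit override — because only the
mineral pathway plausibly competes with microbial uptake in oxic
sediments. Global sums use compensated (Kahan) summation: a realistic
grid adds ~10⁵–10⁶ terms spanning several orders of magnitude, and the
sum must be independent of cell order to 10⁻¹² relative.

## 5. Monte Carlo uncertainty propagation

Each of the four parameters — rate (nmol l⁻¹ yr⁻¹), activation energy
(J mol⁻¹), molecular weight (g mol⁻¹), carbon content — gets a uniform
sampling interval built by one rule: take the min/max of the observed
or literature values, widen each side by one standard deviation, and
replace a negative lower bound with 10⁻¹⁵. The default ranges:

| parameter | values | SD used | default interval |
|---|---|---|---|
| rate | 21.4, 29.0 (mineral, 2.5 g l⁻¹) | 5.1 (larger printed SE) | [16.3, 34.1] |
| activation energy | 40–180 kJ mol⁻¹ stand-in list | sample SD of list | [10⁻¹⁵, ≈229 kJ mol⁻¹] |
| molecular weight | sphere MW at 3.25 and 4.36 nm | MW spread from triangular radius SD | ≈[0.93, 3.50] × 10⁵ |
| carbon content | 0.40 | 0.01 instrument uncertainty | [0.39, 0.41] |

The activation-energy list is an explicit stand-in: collated literature
values for Maillard reactions span roughly this range, but the exact
list belongs to the configuration, not the code. Note the ±1 SD rule
clamps its lower bound at the 10⁻¹⁵ floor, so near-barrierless draws do
occur; they simply reproduce the laboratory rate at every temperature.

**Sampling modes.** `shared_draws` (default) draws one parameter
quadruple per run and applies it to every cell: the four parameters are
physically global properties of GPS chemistry, so their uncertainty
must not average out over space. `per_cell_draws` gives every cell
independent draws each run — a literal per-grid-point reading — under
which the spread of global totals shrinks with the number of cells.
Both are implemented; the run report records which was used. On the
same grid the shared mode's coefficient of variation is invariant to
grid refinement while the per-cell mode's falls ~1/√n_cells — the test
suite asserts this contrast because it is the entire reason the mode
matters.

**Confidence interval.** The per-run global totals are summarised by
mean ± t₀.₉₇₅,ₙ₋₁·SD/√n (a Student-*t* interval on the mean, the
stated convention), with the raw 2.5/97.5 empirical percentiles
reported alongside: the *t*-interval answers "how well is the mean
determined", the percentiles "how wide is the parametric spread".

**Reproducibility.** One master seed spawns a named L'Ecuyer-CMRG
substream per parameter, so draws are independent of iteration order
and every result (and every file the CLI writes) is byte-identical for
a given seed and configuration; the caller's RNG state is saved and
restored. Reports contain no timestamps for the same reason.

## What the synthetic generators emulate — and what they do not

`simulate_margin_grid` reproduces the *structure* the analysis assumes:
a depth mixture over shelf (default 60 % of active cells, 5–200 m) and
slope (200–1,000 m), porosity ~ N(0.70, 0.08) clipped to [0, 1],
temperature falling with depth and latitude (T(°C) = 15 − 3·log₁₀d −
12·|lat|/90 + N(0, 1), truncated to [−2, 30] °C), 10 % of cells active,
and optional rescaling of areas to the real shelf + upper-slope extent
(~3 × 10¹³ m²), which puts the total reactive pore-water volume within
a factor of two of the 1.2 × 10¹⁴ l obtained from real datasets. The
temperature and porosity coefficients are qualitative-realism defaults,
not fits to climatology. `simulate_incubation` produces linear growth
with Gaussian noise floored at zero;
`simulate_reported_incubations` sets each condition's noise so the
fitted standard error matches the published one, plus a baseline offset
of three noise SDs so the zero floor does not censor early samples.
`simulate_dls_radii` uses a triangular distribution — the minimal
distribution matching the reported support and peak.

Consequently, passing tests demonstrate the *correctness of the
machinery* — regression, unit algebra, grid accounting, Arrhenius
scaling, sampling, interval construction — under controlled conditions.
They do not validate real-world magnitudes: the global flux obtained on
synthetic inputs (≈ 0.19 Tg C yr⁻¹ under the defaults, as the
acceptance script computes) reflects the synthetic grid and the
default parameter ranges, and a study-grade estimate requires the real
porosity, bathymetry and bottom-water-temperature datasets plus
measured activation-energy and carbon-content values, fed through
`read_margin_grid()` and the range arguments.

## Problem sizes and runtime choices

The test suite and acceptance script use sizes chosen to exercise every
code path while completing in seconds: 10 × 10 to 90 × 180 grids,
1,000 Monte Carlo runs (matching the stated procedure), 200-replicate
seeded recovery studies, and quadrature cross-checks on fully active
6 × 6–10 × 10 grids. The Monte Carlo cross-check exploits parameter
independence: the expected global total factorises into uniform means
times a per-cell 1-D integral of the Arrhenius factor over the
activation-energy range, evaluated by adaptive quadrature — an oracle
entirely independent of the sampling code.

## Known limitations

* The OPD–depth coefficients, porosity/temperature fields and
  activation-energy list are configuration, not shipped data; defaults
  are documented stand-ins.
* The carbon content default (0.40) is a placeholder pending elemental
  analysis; results scale linearly in it.
* Uniform sampling of ±1 SD-widened ranges is the stated convention;
  it is not a posterior, and no correlation between parameters is
  modelled.
* The estimator upscales mineral-catalysed rates only; dissolved-phase
  catalysis under anoxia (potentially important in ferruginous oceans)
  is outside the oxic-layer model.
* Bioturbation, bio-irrigation and sedimentation-rate variability enter
  only implicitly through the OPD–depth relation.
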