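# maillard

Iron and manganese minerals catalyse the Maillard reaction — the abiotic
polymerization of reducing sugars and amino acids into complex aromatic
macromolecules — at the cold temperatures (~10 °C) of continental-margin
sediments. The large geopolymerized substances (GPS, ≥ 1,000 g mol⁻¹)
this produces resist microbial remineralization, so catalysed
geopolymerization is a candidate mechanism for long-term organic-carbon
preservation in marine sediments.

`maillard` implements the full analysis chain that turns laboratory
incubation kinetics into a global estimate of carbon preserved this way,
for marine biogeochemists who want to refit the rates, swap in their own
gridded data, or interrogate the uncertainty propagation:

1. **Kinetics** — GPS production rates *R*<sub>Lab</sub> (nmol l⁻¹ yr⁻¹)
   by ordinary least squares on incubation time series
   (`fit_rate`), with catalysed/control comparison (`catalysis_factor`).
2. **Particle physics** — GPS diffusion coefficient from the
   hydrodynamic radius via Stokes–Einstein,
   *D* = *k*<sub>B</sub>*T* / (6π·η·*r*<sub>h</sub>), and molecular weight
   MW = *R*³*T*³ρ / (162π²*N*²η³*D*³) (`gps_properties`).
3. **Seafloor grid** — per-cell oxic pore-water volume
   PV = φ·*Z*<sub>O2</sub>·*S* on a lat–lon margin grid (shelf 0–200 m plus
   upper slope 200–1,000 m), with the oxygen penetration depth
   *Z*<sub>O2</sub> from an empirical log–log law in water depth
   (`margin_grid`, `opd_from_depth`).
4. **Upscaling** — Arrhenius scaling of the laboratory rate to each
   cell's bottom-water temperature,
   *R* = *R*<sub>Lab</sub>·exp(−(*E*<sub>a</sub>/*R*<sub>G</sub>)(1/*T* − 1/*T*<sub>Lab</sub>)),
   and the carbon-preservation flux
   *C*<sub>pres</sub> = MW·*C*<sub>cont</sub>·PV·*R* in g C yr⁻¹ per cell,
   summed to Tg C yr⁻¹ globally (`global_c_pres`).
5. **Monte Carlo** — uniform sampling of the four uncertain parameters
   (rate, activation energy, molecular weight, carbon content) over
   ±1 SD-widened ranges, with a Student-*t* 95 % confidence interval on
   the mean global flux (`run_mc`).

Synthetic generators (`simulate_margin_grid`, `simulate_incubation`,
`simulate_dls_radii`) produce inputs with the statistical structure the
analysis assumes, so the whole chain runs without any external download;
real gridded fields can be substituted through the same plain-text grid
format (`read_margin_grid`).

## Worked example

```r
library(maillard)

# 1. fit the birnessite-catalysed rate from a synthetic incubation
ser <- simulate_reported_incubations(seed = 7)
fit <- fit_rate(ser$birnessite_2.5gL)
fit
#> GPS production rate (birnessite_2.5gL)
#>   R_Lab = 32.4 +/- 4.51 nmol l^-1 yr^-1   (R^2 = 0.649, n = 30)
catalysis_factor(fit, fit_rate(ser$control))
#> [1] 183.2925

# 2. GPS particle properties at the DLS peak radius
gps_properties()
#>   hydrodynamic radius: 3.77 nm
#>   diffusion coeff:     6.509e-11 m^2 s^-1 ( 298.15 K )
#>   molecular weight:    202700 g mol^-1

# 3-5. margin grid, upscaling, Monte Carlo
grid <- simulate_margin_grid(seed = 7, total_active_area_m2 = 3e13)
mc <- run_mc(grid, default_parameter_ranges(), n_runs = 1000, seed = 7)
mc
#> Monte Carlo global GPS carbon preservation
#>   1000 runs, mode = shared_draws, seed = 7, 1620 active cells
#>   global mean: 0.1904 Tg C yr^-1
#>   95% t-interval: [0.1828, 0.198] Tg C yr^-1
#>   empirical percentiles: [0.04795, 0.5353]
```

The fitted slope is the laboratory production rate with its standard
error and *R*²; the catalysis factor says the mineral-catalysed reaction
runs two orders of magnitude faster than the catalyst-free control. The
Monte Carlo mean is the global flux of carbon preserved through
mineral-catalysed geopolymerization under the synthetic margin grid and
the default parameter ranges, with the *t*-interval quantifying
parametric uncertainty of the mean and the percentiles showing the full
spread of per-run totals. Its absolute magnitude depends directly on
the grid fields and on the molecular-weight/carbon-content/activation-
energy ranges, which is why all of them are explicit arguments.

A command-line interface wraps the same functions
(`inst/exec/maillard`): `simulate-grid`, `simulate-incubations`,
`fit-rates`, `upscale`, `montecarlo`, `report`. Runs are byte-for-byte
reproducible from their seed and config.

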