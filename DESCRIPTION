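Package: maillard
Title: Iron- and Manganese-Catalysed Geopolymerization and Global
    Organic-Carbon Preservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating how much organic carbon is preserved in
    oxygenated continental-margin surface sediments through Fe- and
    Mn-catalysed Maillard geopolymerization.  The package fits
    geopolymerized-substance (GPS) production rates from incubation time
    series by ordinary least squares, derives GPS molecular weight from
    dynamic-light-scattering hydrodynamic radii via the Stokes-Einstein
    relation, builds gridded continental-margin pore-water volumes from
    bathymetry, porosity and an empirical oxygen-penetration-depth law,
    scales laboratory rates to seafloor temperature with the Arrhenius
    equation, and propagates parameter uncertainty through a Monte Carlo
    procedure to a global carbon-preservation flux with a Student-t
    confidence interval.  Synthetic generators for margin grids,
    incubation series and radius samples allow the whole chain to run
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
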