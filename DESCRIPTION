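Package: fluxleaf
Title: Big-Leaf Ecosystem Properties from Eddy Covariance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derives physical and physiological bulk ecosystem properties
    from half-hourly eddy covariance flux and meteorological measurements
    using a top-down big-leaf framework: aerodynamic and canopy boundary
    layer conductances with Monin-Obukhov stability corrections, surface
    conductance by Penman-Monteith inversion, conditions at the notional
    canopy surface, vegetation-atmosphere decoupling, equilibrium, imposed
    and potential evapotranspiration, energy-balance closure diagnostics,
    water- and light-use efficiency metrics, stomatal slope and sensitivity
    fits, bulk intercellular CO2 and canopy photosynthetic capacity, and
    ecosystem light response curves. Includes the standard meteorological
    helper functions, unit interconversions, a two-stage data filtering
    protocol with growing-season delineation, FLUXNET2015-style readers,
    and a forward big-leaf synthetic flux generator for verification.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
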