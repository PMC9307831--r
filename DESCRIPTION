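Package: treetherm
Title: Thermodynamic Feasibility of Vegetation Beyond Arctic and Alpine Treelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale counterfactual treeline experiment: seeded synthetic
    half-hourly meteorological forcing for subalpine, alpine, sub-Arctic and
    Arctic climate archetypes drives a simplified one-dimensional multi-layer
    canopy, snowpack and soil-column energy-balance model for paired vegetation
    scenarios with and without trees. Model output feeds thermodynamic
    diagnostics (the resultant temperature gradient, signed ecosystem work and
    its four-case classification, snowmelt temperature-inversion episodes) and
    a leaf carbon balance (light- and temperature-limited photosynthesis with a
    winter dormancy switch against Q10 respiration), from which per-scenario
    thermodynamic feasibility verdicts are derived.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
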