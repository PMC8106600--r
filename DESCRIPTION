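Package: riverpec
Title: Geo-Referenced Probabilistic Exposure Modelling of Down-the-Drain
    Chemicals in River Catchments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Steady-state mass-balance simulator for spatially resolved,
    probabilistic predicted environmental concentrations (PEC) of
    down-the-drain chemicals (pharmaceuticals, personal-care products) in
    whole river catchments.  Emissions from households and hospitals are
    routed through wastewater treatment plants into a dendritic river
    network, diluted and degraded by pseudo-first-order in-stream losses,
    and propagated downstream segment by segment.  Monte Carlo simulation
    over river-flow variability (and optionally substance-parameter
    uncertainty) yields per-segment concentration distributions and
    percentiles.  Management scenarios (wastewater re-routing, treatment
    upgrades, consumption change) are compared against a reference run by
    relative-change classification and flow-length statistics against
    environmental quality standards.  Includes a synthetic-catchment
    generator, plain-text catchment database I/O, GeoJSON export, and a
    Dixon Q outlier test for small monitoring series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
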