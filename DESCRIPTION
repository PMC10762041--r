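Package: soilphos
Title: Process-Based Simulation of Phosphorus Pools in Agricultural Soils
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the temporal evolution of phosphorus (P) pools in
    cropland and grassland topsoils (0-0.3 m) by combining annual P
    input/output budgets built from driver data (fertilizer, manure, plant
    uptake and residues, atmospheric deposition, sewage sludge, erosion)
    with a daily seven-pool soil P dynamics model (Freundlich
    sorption/desorption, occlusion, weathering, mineralization) and annual
    land-use-transition pool mixing. Includes pedotransfer-style
    parameterization of exchange rates from soil properties and
    steady-state pool fractions, a Monte-Carlo ensemble machinery that
    propagates driver uncertainty into coefficient-of-variation maps, a
    self-consistent synthetic world generator so the full pipeline runs
    without external data, and evaluation utilities (unit conversions,
    soil-test P conversions, decile/rank map comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
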