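Package: nicheflux
Title: Metabolic Niche Projection and Environment-Coupled Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples genome-scale metabolic models to gridded environmental
    forcing through the metabolic niche: the projection of the steady-state
    flux polytope onto environmentally relevant exchange reactions (nutrient
    uptakes, carbon fixation, biomass). Provides an exact linear-programming
    core for flux balance and flux variability analysis, support-function
    refinement to construct exact low-dimensional niche polytopes, growth
    extraction under nutrient-bioavailability bounds, bi-level auxiliary flux
    ranges at fixed optimal growth, resource-constraint and glycogen-storage
    diagnostics, dissolved-organic-carbon secretion scoring, synthetic
    toy-model and environment-grid generators with known analytic optima, and
    readers/writers for SBML-FBC, a JSON toy-model dialect and
    environment/result tables, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
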