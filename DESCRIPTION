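Package: treedyn
Title: Stock-Flow Simulation of Street-Tree Planting Policies, PM Absorption and Species Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A system-dynamics (stock-flow) model of urban street-tree
    populations under replacement-planting policies. Tree stocks are
    continuous per-species counts turned over at a fixed replacement
    period; replacement plantings are allocated by status-quo,
    single-species-priority, or fixed-mix policies. From the simulated
    composition trajectories the package computes monthly particulate
    matter (PM) absorption (flat or leaf-phenology-seasonal), the Shannon
    species-diversity index, winter absorption means, and multi-criteria
    scenario rankings. Ships the nine published planting scenarios for a
    208-tree street segment in Suwon, South Korea, a closed-form oracle
    for priority-replacement dynamics, seeded synthetic-data generators
    for property testing, and YAML/JSON configuration plus CSV trajectory
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
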