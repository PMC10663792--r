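Package: canopyflux
Title: Linking Vertical Forest Structure to Carbon Fluxes with a Gap Model
    and Boosted Regression Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A virtual-experiment framework for tropical forests. An
    individual-based forest gap model simulates succession from bare ground
    to equilibrium for replicate 200 x 200 m plots, emitting per-tree annual
    gross and net primary production (GPP, NPP) and above-ground biomass.
    Tree lists are converted into vertical biomass profiles at configurable
    layer widths (2-100 m) and horizontal cell sizes (0.04-4 ha), and
    boosted regression trees with a Laplace error structure are trained to
    predict GPP, NPP and carbon turnover time from those profiles, across
    all resolution combinations and for disturbed versus mature forests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
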