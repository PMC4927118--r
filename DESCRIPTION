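Package: cafbar
Title: Constrained Allocation Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Growth-rate maximization on genome-scale metabolic networks under
    mass balance, flux bounds, and a single genome-wide proteome-allocation
    constraint coupling carbon intake, enzymatic fluxes and ribosome synthesis.
    Implements the split-flux linear-programming formulation, homogeneous and
    heterogeneous (log-uniform) enzyme-weight schemes with calibration to a
    target maximal growth rate, ensemble averaging over weight realizations,
    carbon- and translation-limitation sweeps, growth-rate-dependent biomass
    iteration, parsimonious FBA references, flux-overlap statistics, acetate
    onset fitting and growth yields. Reads COBRA-style JSON and SBML (with or
    without FBC bounds) and generates self-contained synthetic networks with
    analytic optima for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
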