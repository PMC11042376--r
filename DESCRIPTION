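Package: mitobrush
Title: Loop Extrusion, Bottlebrush Chromatid Models and Hi-C Contact Scaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for mitotic chromosome formation
    by SMC complexes. Provides a discrete 1D lattice engine for loop extrusion
    by condensin I/II and cohesin with configurable rules of engagement
    (bypass, stall, unload, push), constructive coarse-grained builders for
    bottlebrush and helical-cylinder chromatid conformations and cohesed
    sister pairs, Hi-C style contact-map and P(s) contact-scaling analysis
    (log-derivative loop-size estimation, periodic-diagonal detection,
    compartment and dot scoring), in-vivo extrusion-speed estimators, and a
    grid-search fitter of chromatid model parameters to target P(s) curves.
    All inputs can be generated synthetically with seeded generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
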