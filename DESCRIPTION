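Package: fossilhotspots
Title: Detection of Origination, Extinction and Species-Sorting Hotspots in
    the Fossil Record
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of exceptional origination ("species
    factories"), extinction, immigration and local-extinction hotspots in
    spatiotemporal fossil occurrence records. Occurrences are aggregated
    around focal grid points with a linear distance-decay kernel, expected
    event counts are modelled by logistic regression on sampling intensities
    in consecutive time bins, and observed weighted event counts are tested
    against the model with binomial (or exact Poisson-binomial) exceedance
    probabilities. Also provides dental-ecometric reconstruction of net
    primary productivity from community hypsodonty and loph scores, species
    longevity and convex-hull geographic-range metrics, a synthetic
    fossil-record generator for validation, and a pipeline driver for
    NOW-style occurrence tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
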