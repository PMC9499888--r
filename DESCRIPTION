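Package: NMRShiftID
Title: Small-Molecule Identification from Noisy NMR Chemical Shift Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework for studying how much error in predicted
    13C and 1H NMR chemical shifts can be tolerated while still identifying
    small molecules against an in silico reference library. Queries are
    matched to library entries by minimum-cost one-to-one assignment of
    shift lists (Hungarian algorithm over squared differences), scored by
    per-nucleus RMSE combined as a geometric mean, and ranked. Includes a
    synthetic library generator emulating metabolite shift statistics,
    Gaussian noise injection, Monte-Carlo sweeps of identification rate
    versus noise level for pure samples, mixture (2-3 compound)
    identification by count-sum tuple enumeration, and carbon/proton error
    trade-off contour analysis with reciprocal curve fitting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
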