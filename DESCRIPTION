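Package: micpkin
Title: Kinetic Profiling and Isolate Selection for Microbially Induced
    Calcium Carbonate Precipitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling ureolytic bacterial isolates used in
    microbially induced calcium carbonate precipitation (MICP). Implements
    a weighted standard-score statistic over min-max normalized assay
    panels for ranking candidate isolates, closed-form kinetic models for
    first-order ureolysis, four-parameter sigmoidal trajectories (pH,
    viable-cell counts, precipitate mass) and first-order free-calcium
    depletion, multistart bounded nonlinear least-squares estimation of
    their parameters with goodness-of-fit and replicate-based lack-of-fit
    diagnostics, a synthetic trajectory and assay-panel generator for
    validation by parameter recovery, and a pipeline that assembles
    per-strain coefficient reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
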