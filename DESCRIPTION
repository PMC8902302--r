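Package: bedrestvar
Title: Separating Measurement Uncertainty, Between-Subject and
    Within-Subject Variation in Bed Rest Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance decomposition of musculoskeletal responses to
    experimental bed rest measured by peripheral quantitative computed
    tomography (pQCT). Implements the duplicate-baseline estimator of
    measurement uncertainty, the superposition decomposition of observed
    percent-change variance into measurement uncertainty and individual
    response uncertainty, a donor-study borrowing rule for studies without
    duplicate baselines, responder classification against measurement-based
    confidence intervals, inter-site correlation analysis of within-subject
    variation, endocortical geometry regressions, and a Gaussian worst-case
    projection of crew bone loss. Ships a synthetic multi-study cohort
    generator so the full pipeline runs and is testable without access to
    the original scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
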