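Package: duallist
Title: Two-List Record Linkage and Capture-Recapture for Attacks on Health Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing two independently collected event datasets of
    publicly reported attacks on health care. Provides a normalised event
    record model with the WHO Health Emergencies (WHE) country registry,
    inclusion filtering with machine-readable exclusion reasons, rule-based
    cross-source record linkage (definite / possible / unique classification
    with adjudication), two-list capture-recapture estimation of the total
    event universe (Chapman estimator and a published variant, with variance
    and confidence intervals), and descriptive comparison tables. A synthetic
    dual-source event generator with ground-truth match keys makes every
    pipeline stage testable without access to the underlying surveillance
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
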