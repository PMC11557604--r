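Package: traumasim
Title: Simulation-Based Evaluation of Trauma Prevalence Estimators for
    Incomplete Skeletal Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating cranial trauma prevalence from incomplete
    human skeletal remains and for evaluating estimator performance by
    simulation. Implements the conventional crude-frequency approach, which
    restricts samples to specimens above a minimum completeness threshold,
    and a binomial generalized linear model with a log link that uses
    specimen completeness as a continuous covariate. A Monte-Carlo harness
    generates once-complete two-sample cranial datasets from a reference
    pool of real-life blunt-force trauma cases, degrades them with
    taphonomically weighted missing data drawn from a clipped normal
    distribution, and summarises the accuracy, precision, relative-pattern
    fidelity and production rate of both estimators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
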