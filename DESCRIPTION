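Package: birdhab
Title: Forest Degradation, Bird Habitat Back-Casting and Population Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking forest degradation to bird habitat and
    population change. Implements harmonic-regression reflectance features
    with breakpoint detection, presence-only maximum-entropy species
    distribution models with spatial-block validation, annual habitat
    back-casting with error-minimizing binarization thresholds and
    route-buffer accounting, hierarchical Bayesian overdispersed-Poisson
    abundance trend models (route-level Sauer-Link variant), and
    breeding-pairs-lost impact summaries. A synthetic-landscape simulator
    generates reflectance series, species occurrences and route counts with
    known ground truth so every stage can be verified end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rjags,
    coda,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
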