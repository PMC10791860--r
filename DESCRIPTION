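Package: epimoderate
Title: Epigenetic Pacemaker Models and Detection of Epigenetic Aging Moderators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the epigenetic pacemaker (EPM), a model in which DNA
    methylation at each CpG site is linear in a shared latent per-sample
    epigenetic state, using a fast conditional expectation-maximization
    algorithm. Provides a trait-associated methylation simulator for
    benchmarking the sensitivity of epigenetic state and penalized-regression
    epigenetic age to factors that accelerate or decelerate aging (sex-like
    binary exposures, continuous health factors, cell-type composition), a
    site-selection pipeline (correlation and error screens,
    affinity-propagation clustering of per-site regression residuals,
    cross-validated cluster evaluation and merging), an elastic-net epigenetic
    clock comparator, and ordinary-least-squares moderation analysis of fitted
    states and ages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
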