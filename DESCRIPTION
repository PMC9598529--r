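Package: composcore
Title: Autoencoder and PCA Composite Scoring for Clinical Outcome Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Distills a battery of eight clinical outcome measures collected
    under a two-condition crossover design into a single health composite per
    subject-condition record, using a seven-layer bottleneck-of-one
    autoencoder trained with full-batch Adam on the mean squared
    reconstruction error, and compares it against a first-principal-component
    composite. Includes standard-scaling utilities, explained-variance
    evaluation under repeated 90/10 splits, hyper-parameter grid search,
    sign alignment of composites to the per-measure direction of improvement,
    a two-level repeated-measures ANOVA of the condition effect (paired-t
    reduction), figure-ready arrow-plot data, and a calibrated latent-factor
    synthetic cohort generator for fully reproducible analyses when the
    underlying clinical data are unavailable.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
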