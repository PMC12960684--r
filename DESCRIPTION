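Package: oatopt
Title: Animated Oat Optimization with Genetic Operators and Weighted
    Classifier-Ensemble Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bound-constrained global optimization with the animated oat
    dispersal metaheuristic, optionally enhanced with differential crossover,
    non-uniform mutation and greedy replacement (EAOO-GA), alongside reference
    optimizers (differential evolution, a real-coded genetic algorithm,
    random search). The optimizers drive simplex-constrained weight tuning of
    soft-voting classifier ensembles, with conventional fusion rules (mean,
    product, hard voting, and others) as baselines. Also included: pure-array
    squeeze-and-excitation channel recalibration and Grad-CAM map combination,
    min-max image normalization, grayscale augmentation transforms, SMOTE
    class balancing, and seeded synthetic-fixture generators so every
    component is testable without any imaging dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
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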