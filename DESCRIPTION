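Package: breathelearn
Title: Interoceptive Learning and Metacognition Analysis for Breathing Tasks
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing binary interoceptive (breathing) learning
    experiments. Implements Rescorla-Wagner and two- and three-level
    Hierarchical Gaussian Filter perceptual models with a unit-square
    sigmoid response model, maximum a posteriori fitting with Laplace
    approximations to the log model evidence, random-effects Bayesian model
    selection with protected exceedance probabilities, parameter-recovery
    and model-identifiability simulation studies, type-2 signal-detection
    metacognition metrics (meta-d', Mratio) for a filter detection task,
    normality-gated group comparisons, and a permutation-tested principal
    component analysis of multimodal cohort tables. A synthetic-data module
    generates task schedules, simulated learning agents, staircase-driven
    detection observers, and multimodal cohorts so the full pipeline runs
    without access-restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
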