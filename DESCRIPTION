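Package: ClockInk
Title: Graphomotor Feature Analysis for Digitally Captured Clock Drawings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing timestamped pen-stroke recordings of the
    clock drawing test. Provides an S4 data model and delimited/JSON I/O for
    pen trajectories, a registry-based extractor for graphomotor and temporal
    features (completion time, think/ink partition, inter-stroke latencies,
    least-squares clock-face geometry, hand-angle error), rank-based inverse
    normal transformation, a covariate-adjusted mass-univariate association
    scan against a neuropsychological battery with Bonferroni control,
    weighted composite-score construction from significant features, logistic
    models for mild cognitive impairment, and a parametric synthetic-cohort
    generator in which a latent cognition trait drives both drawing
    kinematics and test scores, so the whole pipeline is exercisable without
    any restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StatisticalMethod, Regression, Epidemiology
RoxygenNote: 7.3.3
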