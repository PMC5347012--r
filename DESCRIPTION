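Package: dsindex
Title: Disease Severity Index from Brain Morphometry via OPLS Discriminant
    Modelling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a multivariate disease severity index for preclinical
    Alzheimer's disease research. An orthogonal projections to latent
    structures (OPLS) discriminant model is trained on regional brain
    morphometry (cortical thickness and volume plus subcortical volumes) to
    separate Alzheimer's disease patients from healthy controls under
    stratified 7-fold cross-validation, and unseen subjects (e.g. individuals
    with subjective memory decline) are projected onto the model to obtain a
    per-subject severity index on a 0 (control-like) to 1 (disease-like)
    scale. Subjects are subtyped at a 0.5 cutoff and subtypes are validated
    against longitudinal follow-up via progression proportions,
    Kaplan-Meier curves, log-rank tests and Benjamini-Hochberg correction.
    A seeded synthetic-cohort generator with a configurable planted atrophy
    pattern makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    survival,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Classification, Survival, StatisticalMethod, Alzheimer
RoxygenNote: 7.3.3
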