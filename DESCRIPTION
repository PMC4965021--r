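Package: bodysom
Title: Body Shape Typing from 3D Anthropometry with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage self-organizing map (SOM) pipeline for large
    anthropometric cohorts measured by 3D body scanners. A feature SOM
    aggregates correlated raw body measures into a small set of
    meta-measures via U-matrix watershed clustering; a second, body SOM
    clusters participants on their meta-measure profiles into body types.
    Includes the three-step missing-value preprocessing, height and
    Z-normalization, classical body indices (BMI, WHR, WHtR, ABSI),
    subsampled consensus clustering with intra-/inter-cluster consensus
    statistics and stability-versus-cohort-size curves, bodygram (polar
    profile) construction, body-map stainings and tertile maps, and a
    synthetic-cohort generator with planted measure blocks and body-type
    mixture components for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
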