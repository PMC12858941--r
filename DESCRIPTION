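Package: traitmapper
Title: Community Trait Mapping from Surveys, Occurrences and Trait Databases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds gridded community-weighted mean (CWM) and
    frequency-weighted mean (FWM) plant trait layers from vegetation survey
    tables, opportunistic species occurrence records and a species trait
    database, and models them against environmental predictor stacks with
    missing-value-tolerant gradient-boosted trees. Validation uses spatially
    blocked cross-validation with hexagon folds sized by the fitted spherical
    semivariogram range and balanced over Kolmogorov-Smirnov simulations.
    Uncertainty products include per-pixel ensemble coefficient of variation
    and the dissimilarity-index / area-of-applicability mask. A synthetic
    world generator with known ground truth (autocorrelated environments,
    niche-driven communities, clustered surveys, biased occurrences,
    incomplete trait measurements) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xgboost,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
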