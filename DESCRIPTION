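Package: foldbase
Title: Lifespan Baselines for Cortical Folding Morphometrics from Multisite MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives the near-independent cortical folding variables K, S and
    I from hemisphere and lobe morphometrics (average cortical thickness,
    total pial area, exposed area), harmonizes heterogeneous multisite
    cohorts with linear mixed models carrying per-(sample, region) random
    intercepts, budgets measurement uncertainty into natural, repeated-
    measure and between-sample components, selects the age-trend model by
    numerically marginalized Bayesian evidence, and estimates lifespan
    baselines, aging rates, group slope contrasts and per-decade
    self-similarity exponents.  A synthetic multisite cohort generator with
    known ground truth makes every stage testable without access to
    restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
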