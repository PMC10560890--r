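Package: ctcstab
Title: Vaccine Stability Evaluation and Minimum Release Potency under
    Extended Controlled Temperature Conditions
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical evaluation of vaccine stability data collected
    under real-time cold-chain storage (2-8 degrees C) and extended
    controlled temperature conditions (ECTC, 40 degrees C). Provides the
    study-design containers and CSV input/output, a calibrated synthetic
    stability-data generator, regression-assumption diagnostics
    (mean-range transformation selection, Shapiro-Wilk, Breusch-Pagan,
    White, Durbin-Watson, influence measures, partial-residual linearity),
    ICH Q1E batch-poolability testing at alpha = 0.25, shelf-life
    evaluation via the 95 percent confidence band of the mean regression
    line, and minimum release potency (MRP) calculation with a combined
    uncertainty that propagates slope-estimation error and residual
    variability across both storage phases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
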