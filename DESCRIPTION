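Package: dendroiso
Title: Tree-Ring Stable Carbon Isotope Proxy Records from Radiocarbon-Dated Cores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds rainfall proxy records from stable carbon isotope (delta 13C)
    series measured along tree cores that lack countable annual rings. Provides
    radiocarbon calibration with highest-posterior-density intervals (pre-bomb
    and post-bomb F14C regimes), tie-point-constrained piecewise-linear age
    models with growth-hiatus support, atmospheric Suess-effect and
    pre-industrial (ci/ca based) corrections of the isotope series, robust
    21-year Tukey biweight smoothing and multi-tree compositing with standard
    errors, and the accompanying statistics: Mann-Kendall and least-squares
    trend tests, mean-shift changepoint detection (PELT and binary
    segmentation), moving-average comparison and windowed Pearson correlation
    against climate forcing indices. A synthetic-data generator with known
    ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
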