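Package: cohortcomp
Title: Counterfactual Socioeconomic Composition of Birth Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Interrupted-time-series Poisson modelling of weekly or monthly
    live-birth counts by socioeconomic group, counterfactual totals for a
    pandemic-conception birth cohort, observed-versus-counterfactual
    compositional differences in percentage points, and Monte-Carlo percentile
    confidence intervals for those differences. Includes a synthetic
    birth-register generator with known ground truth so the whole pipeline can
    be exercised and validated without access to restricted national registers,
    plus a configuration-driven end-to-end pipeline with tabular and graphical
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
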