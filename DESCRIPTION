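Package: workergf
Title: Parametric g-Formula for Occupational Cohort Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the parametric g-formula for discrete-time occupational
    cohort mortality analyses subject to healthy worker survivor bias. Provides
    a synthetic occupational-cohort generator with a known data-generating
    process (including the exposure to employment to exposure confounding
    loop), person-period expansion with lagged cumulative-exposure windows and
    restricted cubic spline bases, pooled logistic and proportional-odds
    discrete-time hazard models fit by Newton-type maximum likelihood, a Monte
    Carlo simulation engine for hypothetical workplace interventions on
    exposure, competing-risks cumulative incidence estimation with late entry,
    risk differences and excess deaths per 1,000, worker-level percentile
    bootstrap confidence intervals, and natural-course calibration diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    survival,
    splines,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
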