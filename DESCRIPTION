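Package: wastunt
Title: Longitudinal Analysis of Wasting and Stunting in Young Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for longitudinal analysis of growth faltering in children
    under two years of age from routine clinic anthropometry. Computes and
    inverts LMS (Box-Cox) z-scores against a pluggable growth reference,
    applies reproducible cohort-cleaning rules (implausible z-scores, extreme
    between-visit changes), tabulates cross-sectional prevalence of wasting,
    stunting and their concurrence by age and sex, classifies per-season
    wasting episodes across an infant's first two wet seasons, fits
    mixed-effects growth curves with natural-spline age trends and Fourier
    (cosinor) seasonality including individual seasonal-amplitude random
    effects summarised by a coefficient of cyclic variation, fits logistic
    models for stunting risk, and fits time-lagged multilevel logistic models
    linking wasting to subsequent stunting. Includes a seeded synthetic cohort
    generator with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    splines,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
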