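Package: cbready
Title: Childbirth Service Readiness Indices from Health Facility Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs composite childbirth service readiness indices from
    binary item-availability data collected in health facility surveys.
    Three item-selection frameworks (SARA obstetric tracer items, the DHS
    analytical-study indicator set, and an expanded set mapped to the WHO
    standards for improving quality of maternal and newborn care) are each
    aggregated by simple addition, domain-weighted addition and principal
    components analysis, yielding nine indices per facility tier. Includes
    the item-selection diagnostics used to build standards-based indices
    (per-item availability, near-universal screening, two-parameter
    logistic item response models fitted by marginal maximum likelihood,
    interitem correlation, Cronbach's alpha), a full index-comparison
    battery (distributional summaries, floor and ceiling effects, tie
    analysis, Bland-Altman agreement, Spearman correlation with delivery
    volume, domain deconstruction), and a synthetic facility cohort
    generator for end-to-end testing without access-restricted survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
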