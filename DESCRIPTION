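Package: sidscreen
Title: Screening Infant Causes of Death for SIDS-Like Mortality Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening harmonized infant cause-of-death groups
    against sudden infant death syndrome (SIDS). Joins ICD-9 and ICD-10
    cause codes into harmonized groups as connected components of the
    General Equivalence Mappings (GEM) crosswalk graph, reads linked
    birth-infant death records from fixed-width or delimited layouts,
    computes normalized weekly age-at-death profiles and normalized annual
    mortality series, screens causes by Pearson correlation with a SIDS
    reference profile and trend, and regresses age at death on gestational
    age with era and ICD-version robustness subsets. A synthetic
    vital-statistics cohort generator with planted statistical structure
    makes every stage verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
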