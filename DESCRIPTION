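Package: pvsignals
Title: Pharmacovigilance Signal Detection for Spontaneous-Report Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A case/non-case disproportionality pipeline for FAERS-style
    spontaneous adverse-event reports: quarterly ASCII ingestion with
    referential-integrity validation, two-stage deduplication (CASEID
    recency and field-match clones), reporting odds ratios with Woolf
    confidence intervals, sex- and age-stratified relative RORs,
    time-to-onset and seriousness contrasts, and drug-drug-interaction
    signal scores (lift, conviction, additive and multiplicative
    interaction, combination risk ratio). A synthetic report generator
    with planted signals of known strength makes every stage testable
    without access to the full database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
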