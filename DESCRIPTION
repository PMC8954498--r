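Package: faersforge
Title: Curation and Disproportionality Analysis of Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for turning raw FAERS/LAERS-style quarterly extracts of
    spontaneous adverse event reports into an analysis-ready dataset: schema
    harmonization of the legacy and current extract layouts, two-stage case
    deduplication (latest-version retention followed by cross-source matching
    on an eight-field signature with an allow-one-mismatch rule), drug-name
    standardization to single active ingredients against a pluggable
    RxNorm-style vocabulary, and pre-computed disproportionality statistics
    (reporting odds ratio, proportional reporting ratio, Yates-corrected
    chi-squared, and the information component with closed-form credibility
    bounds) for every drug-event pair. A synthetic-extract generator with a
    ground-truth ledger makes the whole pipeline testable without any
    download of the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
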