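Package: comorbnet
Title: Comorbidity Discovery from Adverse-Event Reports via Rule Mining
    and Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering disease comorbidities
    from spontaneous adverse-event case reports (FAERS-style quarterly
    tables). Case reports are de-duplicated and term-normalized, an
    opioid-use-disorder cohort is flagged from drug and reaction lexicons,
    frequent disease patterns are mined with an FP-growth implementation
    and turned into lift-filtered association rules, a disease comorbidity
    network is built by clique expansion of the rules, and diseases are
    prioritized by random walk with restart from the cohort seed, with
    decile evaluation against a gold-standard list. A stratified
    case-control arm estimates Cochran-Mantel-Haenszel common odds ratios
    with Robins-Breslow-Greenland confidence intervals on population-level
    2x2 tables, including handling of small-cell suppression. A synthetic
    data generator with planted comorbidity structure and known common
    odds ratios makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
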