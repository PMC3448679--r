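Package: infoseekr
Title: Modeling Health Information-Seeking Journeys in Search Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how people seek health information online,
    built around cancer-related query logs. Provides a synthetic query-log,
    contact-graph and crowd-label generator with realistic heavy-tailed
    structure; cohort-construction rules (lexicon matching, severity
    partition, high-interest filtering); crowd-label aggregation and a
    vector-space ambiguity analysis; discrete-emission hidden Markov models
    over page categories with holdout selection of the number of hidden
    states; co-search analysis on a proxy social network (enrichment over a
    permutation null, disease overlap, lag and duration contrasts); and a
    regression of query-log disease frequency on registry incidence,
    survival and age at diagnosis.
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
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
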