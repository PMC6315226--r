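Package: cbsmatch
Title: Demographic Record Matching and Deduplication for Case-Based
    Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Person-matching and deduplication for longitudinal health
    records that lack a universal identifier, as used in HIV case-based
    surveillance. Standardizes demographic fields, builds phonetic match
    keys (American Soundex, double metaphone), matches records
    deterministically via pseudo-unique keys and clinic numbers or by
    score (Jaro, Jaro-Winkler, weighted Levenshtein and
    Damerau-Levenshtein similarity against a threshold with an age
    comparator), blocks records by care-cascade scenario, resolves
    duplicate clusters to completeness-maximized retained records, and
    ships a synthetic case-record generator with ground truth for
    precision/recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
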