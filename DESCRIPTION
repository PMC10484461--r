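Package: kcnlit
Title: Keyword Co-Occurrence Network Analysis of Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses keyword co-occurrence networks (KCNs) from
    bibliographic article records. Provides corpus ingestion with duplicate
    removal, Porter-stemming keyword normalization, per-time-window weighted
    co-occurrence network construction, weighted network statistics (degree,
    strength, average weight versus endpoint degree, weighted nearest-neighbor
    degree, geometric-mean weighted clustering), frequency-rank trend
    classification across time windows, Apriori association-rule mining over
    article keyword sets, and a seeded synthetic-corpus generator with
    machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
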