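Package: litjump
Title: Data-Driven Literature Relevance Scoring and Rank-Jump Detection for
    Drug-Target Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines a corpus of dated biomedical abstracts for frequently used
    multi-word phrases (n-grams), clusters phrases that look alike or are used
    in the same context into 'semantic concepts' with the Markov cluster
    algorithm, and weights each concept by its average pointwise mutual
    information with a core set of disease-associated proteins selected by
    Fisher's exact test. Articles are scored by summing the weights of the
    concepts they contain; proteins are ranked weekly from the best article
    mentioning them over a sliding five-year window; and statistically
    significant weekly improvements in rank ('high-jumpers') are flagged
    against the empirical distribution of historical rank changes. Includes a
    seeded synthetic-corpus generator with planted ground truth for end-to-end
    validation, and a staged command-line pipeline with cached intermediates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    igraph,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
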