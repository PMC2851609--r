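Package: genenorm
Title: Gene and Protein Mention Recognition and Dictionary Normalization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognition and normalization of gene and protein mentions in
    biomedical text. Mentions are extracted with a trainable case-based
    reasoning tagger that retrieves stored (token, category, preceding
    category) cases by verbatim token or by token shape; mentions are mapped
    to database identifiers by flexible (variation-based exact) matching
    against Entrez gene_info-style dictionaries or by a trainable
    approximate string matcher over synonym pair features; ambiguous
    identifiers are resolved by comparing the article text against
    per-gene token documents. Reads and writes the BioCreative 2 Gene
    Mention corpus dialect with its space-ignoring character offsets, and
    ships seeded fixture generators so every stage can be trained and
    tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
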