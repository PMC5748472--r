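Package: chvsimplify
Title: Lexical Simplification of Radiology Reports with a Consumer
    Health Vocabulary
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map clinical terms in radiology report text to
    concepts of a consumer health vocabulary distributed as UMLS
    Metathesaurus MRCONSO records, replace mapped terms with their
    consumer-preferred equivalents (marked with square brackets), and
    evaluate the result with content-coverage and stem-based
    lexical-similarity statistics, including categorisation of concepts
    the vocabulary does not cover. Concept hits can be read from MetaMap
    fielded MMI output or produced by a built-in dictionary longest-match
    mapper. A synthetic corpus generator with known ground truth makes the
    whole pipeline testable without licensed vocabulary releases or an
    external concept mapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
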