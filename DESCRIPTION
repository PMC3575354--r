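Package: clintypes
Title: Layered Annotation Types and Clinical Element Semantics for Clinical NLP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A standalone implementation of a layered annotation type system
    for clinical text, spanning lexical, syntactic, textual-semantic and
    referential-semantic (Clinical Element Model based) representations.
    Provides a declarative schema registry with subsumption and instance
    validation, a per-document annotation store with type-aware indices and
    canonical JSON serialization, the normative 100-type inventory across
    seven namespaces, a resolution bridge that turns coreferring text
    mentions into normalized document-level clinical elements (concept
    disambiguation, attribute merging, relative-date normalization, relation
    lifting), readers and writers for the Clinical Element Model XML dialect,
    and a synthetic clinical-document generator plus command-line tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    lubridate,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
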