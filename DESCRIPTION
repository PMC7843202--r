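Package: clinnorm
Title: Clinical Term Normalization with Learned Edit Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Normalizes free-text clinical term mentions to concept
    identifiers (CUIs) in a synonym lexicon such as a UMLS/SNOMED CT/RxNorm
    extract. Matching proceeds through exact lookup, automatically learned
    character- and word-based edit patterns (generalized minimal edit
    alignments between synonyms, scored by positive and negative rewrite
    counts), subconcept matching over n-gram subterms, and learned
    semantic-type disambiguation rules. Includes a synthetic lexicon
    generator with planted term variations so every stage can be exercised
    without licensed terminology resources.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
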