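Package: dtclass
Title: Dependency-Tree Pattern Classification of Opinionated Sentences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns ranked dependency-tree matching patterns from labeled
    sentences and uses them to assign three-valued opinion labels
    (yes / no / neutral) to new sentences, as in aspect-based analysis of
    patient reviews of doctors. Implements a subset of the semgrex pattern
    language with a brute-force-verified matcher, pattern extraction by
    pruning trees to high-information-gain words with negation preserved,
    pattern ranking by weighted (macro-averaged) accuracy, a
    highest-ranked-match classifier with majority or pluggable backup
    fallback, stratified cross-validated evaluation, readers and writers for
    CoNLL-U, a bracketed tree dialect and a JSON-lines corpus format, and a
    synthetic gold-tree corpus generator with planted discriminative motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
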