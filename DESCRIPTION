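Package: addrlink
Title: Probabilistic Linkage of Free-Text Addresses to a Structured Gazetteer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links semi-structured free-text addresses (as recorded in health
    and administrative registers) to unique property identifiers in a
    structured UK-style address gazetteer. Combines gazetteer augmentation
    with alternative address forms, fuzzy field-to-text alignment
    (Needleman-Wunsch global alignment with Damerau-Levenshtein token
    equivalence), blocking by depth-first search in a layered tree database,
    and a random-forest matching classifier whose out-of-bag vote fraction
    serves as a match confidence score. Includes a synthetic gazetteer and
    address-corruption generator for benchmarking, and an evaluation suite
    (raw and adjusted accuracy, top-k accuracy, precision/recall/F1 across a
    confidence-threshold sweep).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
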