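Package: methsc
Title: CpG Methylation Status Prediction from DNA Composition and
    Sequence Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the binary methylation status of CpG sites from the
    local DNA sequence alone. Fixed-size windows centred on CpG sites are
    encoded as 72 features: 64 overlapping trinucleotide frequencies, GC
    content, and 7 sequence-complexity features read off the subword
    complexity function at rational points chosen via discrete difference
    operations. A linear-kernel support vector machine is trained on
    beta-value-labelled sites, evaluated by stratified cross-validation
    with sensitivity, specificity, accuracy, Matthews correlation and
    rank-based AUC, and its normalized coefficients provide feature
    importance. Includes dataset construction from bedGraph-style
    methylation calls (beta-threshold labelling across stages, window
    extraction from a reference genome, greedy redundancy reduction), a
    region-level profile consistency test against ChromHMM-style
    annotations, and a synthetic genome/methylome generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
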