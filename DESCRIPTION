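Package: orthocodon
Title: Codon and Amino-Acid Usage Signatures in Orthologous Transcriptome Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of orthologous coding-sequence pairs from two
    closely related species to detect thermal-adaptation signatures: amino-acid
    replacement imbalances at non-synonymous positions, A/T versus G/C shifts at
    synonymous third codon positions (GC3/AT3), within-group correspondence
    analysis of synonymous codon usage, and functional-category coverage
    profiling. Includes a local protein aligner with ortholog pairing and
    filtering, codon back-translation and per-column classification, exact
    Fisher and Wilcoxon testing of usage shifts, and a synthetic-data generator
    that produces diverging ortholog pairs with known injected signatures so
    that every stage of the pipeline is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
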