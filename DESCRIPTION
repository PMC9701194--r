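Package: pamdose
Title: PAM Specificity Profiling and Guide Design for Excision-Based Cas9 PAM Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing Cas9 protospacer-adjacent-motif (PAM)
    specificity from excision-based positive-selection reporter assays.
    Simulates randomized-PAM amplicon sequencing libraries under a known
    per-PAM cleavage-activity model, anchors and filters reads (rejecting
    reads with indels near the PAM cassette), counts cassette k-mers, and
    derives enrichment scores, position probability matrices,
    information-content profiles and degenerate IUPAC consensus PAMs.
    Also quantifies fluorescent-reporter editing efficiency, base-editing
    site frequencies via the editing-window maximum, embryo editing
    summaries, and scans FASTA sequences for guide-RNA target sites
    matching a degenerate PAM such as N4GYAT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
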