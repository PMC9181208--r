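Package: pandesign
Title: Panning Enrichment Analysis and Design of Synthetic Antibody CDR Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational design of synthetic antibody libraries
    from phage-display biopanning deep-sequencing data. Extracts
    complementarity-determining regions (CDRs) from pre- and post-panning
    amplicon repertoires using invariant framework anchors, assigns non-H3 CDRs
    to human germline ancestors and compares their panning enrichment, computes
    a per-sequence enrichment score that combines the log2 frequency change
    with a read-count confidence weight, trains per-length ridge models on
    one-hot positional residue features to predict enrichment, simulates
    candidate CDR-H3 sequences from positional amino-acid frequencies while
    excluding post-translational-modification motifs, removes predicted MHC
    class II T-cell epitopes by sliding-window filtering, and assembles
    fixed-length oligonucleotide designs for parallel synthesis. Includes a
    panning simulator with planted ground truth for end-to-end validation.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
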