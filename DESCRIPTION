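Package: regioncall
Title: Region-Based Chromatin Status Calling from Epigenomic Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns per-region chromatin status (present/absent, with
    enrichment score, z-score and FDR-adjusted p-value) to predefined
    fixed-width genomic windows from ChIP-seq, CUT&RUN, CUT&Tag or ATAC-seq
    alignments. Counts fragment midpoints in windows, fits a genome-wide
    Negative Binomial background from genome tiles, locally modulates the
    expected background with a matched control, tests each region with a
    one-sided Negative Binomial tail probability, and integrates multiple
    histone marks into discrete chromatin states (none/active/repressed/
    bivalent). Includes two-sample delta comparisons, expression annotation,
    and a synthetic-data simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
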