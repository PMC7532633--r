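Package: pmdscan
Title: Partially Methylated Domain Detection from WGBS Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects partially methylated domains (PMDs) in whole-genome
    bisulfite sequencing methylomes using a two-state beta-binomial hidden
    Markov model over dynamically sized genomic bins. Bin size is chosen per
    sample so that most bins carry at least 40 read-level observations,
    making segmentations comparable across sequencing depths. Domains are
    obtained by posterior decoding, sharpened to single-basepair resolution
    by a breakpoint likelihood scan, and filtered against an empirical null
    built from a shuffled methylome. Includes sample classification into
    PMD-containing and non-containing methylomes, Jaccard-based stability
    evaluation under read downsampling, escapee-gene annotation with
    observed/expected enrichment tests, and a synthetic-methylome simulator
    with planted domains for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
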