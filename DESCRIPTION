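Package: crisprtrio
Title: Trio-Sequencing Audit of CRISPR-Cas9 Off-Target and On-Target Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing genome-edited animals by family
    trio sequencing: consensus variant filtering across multiple callers
    (site-, genotype- and mask-level hard filters), de novo mutation (DNM)
    discovery with an allele / known-variant / sibling cross filtration
    cascade, genome-wide sgRNA off-target site enumeration under PAM and
    mismatch rules with DNM proximity annotation, structural-variant
    consensus filtering by reciprocal overlap, a binomial power model for
    detecting mosaic mutations at a given sequencing depth, and a synthetic
    trio simulator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
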