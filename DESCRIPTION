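Package: varident
Title: Crop Variety Identification from SNP Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies crop varieties grown in farmers' fields by matching
    genotyping-by-sequencing SNP profiles against a curated reference
    library. Implements identity-by-state (IBS) similarity, genotyping-error
    thresholds calibrated from technical replicates, a six-rule decision
    procedure for varietal assignment with an UNKNOWN fallback, reference
    library deduplication and consistency auditing, Ward hierarchical
    clustering, a masked nonnegative matrix factorization ancestry model
    with cross-entropy selection of the number of groups, Modified Rogers'
    distance with classical multidimensional scaling, and per-group genetic
    diversity indices. Includes a synthetic genotype generator that emulates
    DArTSeq-style biallelic SNP data with genotyping error, missingness,
    admixture and misreported variety names, for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    igraph,
    mclust,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
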