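Package: ibdscan
Title: Robust Detection of Identity-by-Descent Segments from Unphased
    Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects IBD1 and IBD2 segments between pairs of individuals
    from unphased, error-prone diploid genotypes using a windowed
    opposite-homozygote (and mismatch) rate scan with dynamic,
    kernel-density-based threshold selection, followed by kinship
    coefficient estimation and relationship-degree classification.
    Includes a PLINK bed/bim/fam reader and writer, a synthetic panel and
    pedigree simulator with genotyping-error injection, and the standard
    interval-overlap benchmark metrics (recall, power, accuracy,
    length accuracy) for scoring reported segments against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
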