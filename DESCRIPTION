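Package: duplexbc
Title: Duplex Consensus Error Suppression with Semi-Degenerate Barcoded Adapters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for error-suppressed detection of low-frequency variants in
    circulating tumor DNA using semi-degenerate barcoded sequencing adapters.
    Implements the full desk-scale workflow: modelling of IUPAC barcode
    patterns and strand tags, a synthetic read simulator with known truth
    (PCR families, annealing mispairings, polymerase and sequencing errors,
    and strand-asymmetric oxidative damage), read-pair overlap merging and
    tag extraction, PCR-family grouping and single-strand consensus calling,
    duplex matching on the ligation-proximal barcode positions, variant
    allele fraction quantification at targeted sites, and background error
    profiling by substitution class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
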