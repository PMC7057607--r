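Package: dureunite
Title: Duplex Sequencing Consensus Calling with Barcode Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for duplex sequencing data. Reads tagged
    with random 12-mer barcodes on both fragment ends are grouped into
    read families, single-strand consensus sequences (SSCS) are called by
    quality-filtered majority vote, and complementary strand consensi are
    merged into duplex consensus sequences (DCS). Barcodes carrying PCR or
    sequencing errors are rescued by approximate all-vs-all tag matching
    (k-mer partitioned Hamming search), clustering of the resulting barcode
    graph, and per-cluster canonical tag selection, which reunites singleton
    reads with their families and increases duplex yield. The package also
    ships a duplex sequencing simulator with a PCR amplification genealogy
    and a ground-truth log, quality-control diagnostics (inter-barcode
    distance profiles, family size distributions, N-window trimming), and
    truth-log driven evaluation of correction accuracy and consensus error
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    parallel,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
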