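Package: barcodevar
Title: Mitochondrial DNA Barcode Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies within- and between-species mitochondrial sequence
    variation from aligned mitogenomes or COI barcode regions. Computes
    average pairwise difference (APD, the nucleotide diversity pi) with
    pairwise deletion of gaps and ambiguities, builds Klee diagrams
    (indicator-vector correlation heat maps ordered by an unsupervised UPGMA
    tree), classifies variant sites as synonymous or nonsynonymous under the
    vertebrate mitochondrial genetic code, tests whether a barcode-length
    window is representative of the whole protein-coding mitogenome, and
    relates per-species diversity to census population size. Includes a
    seeded simulator of structured mitogenome sets for calibration and
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
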