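Package: metasecretome
Title: Simulation and Analysis of Secretome-Selective Phage Display
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling and analysing secretome-selective
    phage display (sarcosyl selection) experiments on metagenomic
    shotgun libraries.  Provides the clone-lottery selection model and
    enrichment arithmetic, a synthetic-community and clone-library
    simulator with known ground truth, insert-pIII junction and
    reading-frame analysis, heuristic membrane-targeting signal
    classification (signal peptides, lipoboxes, transmembrane
    helices), dbCAN-style CAZyme domain-hit filtering with cellulosome
    module classification and class roll-ups, two-dataset enrichment
    statistics, and best-hit taxonomic binning of BLAST tabular
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
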