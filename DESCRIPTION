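Package: knockintools
Title: Quantitative Screening and Live-Imaging Analysis for Endogenously
    Tagged Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative steps of a CRISPR knock-in tagging
    workflow in cultured cells: seeded simulators for timelapse movies of
    dividing cells, 96-well colony montages and barcoded amplicon reads;
    cortical linescan quantification of cytokinesis (breadth at half maximum,
    cortical-to-cytosolic ratio, signal-to-noise ratio, accumulation timing
    and furrow ingression duration); automated colony detection and well
    calling for clonal recovery screens; read filtering, dual-barcode
    demultiplexing and HDR/indel allele classification for Nanopore-style
    amplicon genotyping; and the matching statistical summaries (Welch's t
    test, Brown-Forsythe and Welch's ANOVA with Dunnett's T3 comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    tools,
    EBImage,
    Biostrings,
    IRanges,
    S4Vectors,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
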