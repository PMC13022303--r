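Package: mechanoquant
Title: Quantitative Analysis of Mechanically Compressed Brain Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking mechanical compression of brain
    organoids to neural-stem-cell behaviour. Covers rheometer force-trace
    analysis (compression-cycle segmentation, peak forces, nominal stress),
    compartmentalised per-pixel immunofluorescence quantification of organoid
    sections (nearest-boundary distances, apico-basal binning, fold-change
    statistics, positive-area and lineage-marker fractions), and
    transcriptomic scoring (per-pathway transcriptional-deviation statistic,
    differential-expression and enrichment filters, single-cell QC, gene-set
    activity scoring with expression-matched references, per-cluster regulon
    fold changes, and score trends over pseudotime). Every input the pipeline
    consumes can be generated synthetically with recorded ground truth, so
    all stages are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
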