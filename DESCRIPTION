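Package: srnakit
Title: Calibration and Discovery Toolkit for Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking small RNA sequencing library preparations
    and for discovering bacterial small non-coding RNAs (sRNAs) from
    strand-specific coverage. Implements equimolar reference-pool
    quantification with cropped-reference exact matching and fold-deviation
    bias statistics; coverage segmentation with a replicate-aware boundary
    crosscheck filter, cross-library merging, overlap counting, trimmed mean
    of M-values (TMM) normalization and CPM filtering; genomic-context
    classification of sRNAs (intergenic, UTR-derived, antisense, intragenic,
    mixed) together with GC-skew and leading-strand statistics; RNA secondary
    structure features (base-pair maximization folding, unstructured 3' end
    length) and a logistic capture-bias model used both to simulate
    structure-dependent ligation bias and to infer it. A synthetic-data
    module generates equimolar pools, toy circular genomes with planted
    sRNAs, and replicate coverage tracks so the whole pipeline is verifiable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
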