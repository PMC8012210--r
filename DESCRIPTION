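Package: chromflow
Title: Scalable Single-Cell ATAC-Seq Analysis from Fragment Files
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@chromflow.dev", role = c("aut", "cre"))
Description: End-to-end analysis of single-cell chromatin accessibility data
    from barcoded fragment files: a chunked on-disk fragment store, per-cell
    quality control with TSS enrichment, synthetic-doublet detection, genome
    tile matrices, iterative latent semantic indexing with LSI projection of
    held-out cells, gene activity scores with bi-directional exponential
    distance decay, sample-aware pseudo-bulk peak calling with iterative
    overlap merging, bias-matched Wilcoxon marker testing, motif scanning and
    chromVAR-style deviation z-scores, Tn5 hexamer-bias-adjusted transcription
    factor footprints, peak co-accessibility and peak-to-gene linkage,
    supervised pseudotime trajectories, and a ground-truthed synthetic
    fragment generator for validating every step without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
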