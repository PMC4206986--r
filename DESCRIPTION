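Package: motifzone
Title: Consensus Transcription-Factor Motif Discovery and
    Intersection-Zone Selection in Orthologous Promoter Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for locating candidate transcription-factor binding
    sites in TSS-anchored promoter windows and distilling them into a
    co-regulation "intersection zone". Promoters are scanned with
    position-weight-matrix log-odds models on both strands; per-sequence
    and dataset-wide motif reports from an ensemble of tools are combined
    under a two-condition consensus rule; genes are selected by a
    mean-count threshold and transcription factors by a top-fraction rank,
    yielding a selected-genes by selected-TFs count submatrix. Includes
    human-mouse orthologous comparison, classification of factors as
    process-specific or pathway-ubiquitous and as high-affinity, and a
    synthetic-data generator that plants binding sites in simulated
    promoter pairs and emulates noisy tool reports, so the whole pipeline
    is testable end to end without external services.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
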