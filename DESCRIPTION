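Package: regtarget
Title: Direct-Target Calling for Transcription Factors from ChIP-seq and
    RNA-seq Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq binding with
    knockdown RNA-seq to call direct regulatory targets. Provides replicate
    concordance and high-confidence peak derivation, summit-window
    read-per-million signal quantification with Spearman correlation and
    hierarchical clustering, fold-change filtering of differential
    expression tables, nearest-peak-to-TSS distance distributions with a
    two-sample Kolmogorov-Smirnov enrichment test against the annotated
    background, a 50-kb direct-target rule split by regulation direction,
    overlap-based (hypergeometric, Benjamini-Hochberg) gene-set enrichment,
    consensus-motif enrichment against a shuffled background, and seeded
    synthetic-data generators with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
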