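Package: zgascreen
Title: Analysis of Pooled CRISPRa Screens with Single-Cell Transcriptomic Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested, self-contained pipeline for pooled CRISPR-activation
    screens read out by single-cell RNA-seq: sgRNA-to-cell assignment from
    amplicon reads with edit-distance error correction and a binomial
    confidence rule, cell and gene quality control with library-size
    normalization and highly-variable-gene selection, repeat-element
    quantification with UMI collapsing, a deterministic multi-view latent
    factor decomposition of gene and repeat expression, per-sgRNA hit calling
    by likelihood-ratio regression of factor values against non-targeting
    controls with FDR control, negative-binomial differential expression with
    a cumulative signature-rank enrichment statistic and empirical
    non-targeting background, and exact Fisher power / sample-size design for
    expressing-cell proportions. Ships a seeded synthetic-screen generator
    with planted ground truth so every stage runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
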