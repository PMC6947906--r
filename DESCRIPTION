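Package: prionscan
Title: Prion-Like Domain Prediction and Sequence-Variation Analysis for
    Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sliding-window prion aggregation propensity scanning of
    protein sequences with FoldIndex intrinsic-disorder gating, merged
    prion-like domain (PrLD) boundary calling, and downstream analyses of
    sequence variation affecting PrLDs: exhaustive pairwise enumeration of
    single amino acid variants with score-range summaries, isoform-level
    comparison of aggregation propensity across splice variants, clinical
    missense variant effect classification, and composition-controlled
    enrichment or depletion statistics for post-translational modification
    types within PrLDs (odds ratios, two-sided Fisher exact tests,
    Benjamini-Hochberg correction). Includes a deterministic synthetic
    proteome and annotation-table generator for testing, and a command
    line interface for batch scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
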