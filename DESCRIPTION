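Package: skewscape
Title: Strand Compositional Asymmetry Profiles Along Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify strand compositional asymmetry (GC and AT
    skew) along protein-coding genes. Computes base-pair-resolution
    metagene profiles anchored at the start or stop codon, binned
    metagene profiles with flanking regions, and sliding-window
    chromosomal skew tracks; tests per-gene 5' to 3' skew change by
    sequence permutation; fits a piecewise-linear three-line model of
    skew along gene bodies by exhaustive grid search; quantifies
    terminal nucleotide and amino-acid usage biases including
    codon-position and fourfold-degenerate-site skews; and relates
    skews to expression and DNA methylation covariates. Includes a
    synthetic gene and genome generator with known embedded skew
    structure for validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    methods,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
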