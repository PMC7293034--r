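Package: nucwrap
Title: Fragment-Level Analysis of Nucleosome Unwrapping from MNase ChIP-seq
Version: 0.1.0
Authors@R:
    person("Mira", "Chen", email = "mira.chen@example.org", role = c("aut", "cre"))
Description: Tools for mapping nucleosome unwrapping states from paired-end
    MNase ChIP-seq fragment data. Computes per-base-pair fragment length
    profiles with peak calling, strand-oriented fragment-center density
    matrices (V-plots) normalized to centers per billion read pairs,
    difference-V-plots between conditions, five-way subnucleosomal fragment
    group ratios in windows around nucleosome centers, hierarchical
    clustering of +1 nucleosomes into unwrapping-state classes with robust
    median/MAD scaling, Spearman correlation of unwrapping ratios with gene
    expression, and orientation of CTCF binding sites on the consensus
    motif. Includes a synthetic fragment generator with known ground truth
    (unwrapping-state mixtures, phased arrays at promoters and CTCF sites,
    footprint fragments, expression-linked unwrapping, and knockdown
    conditions) so the full pipeline can be exercised and validated without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
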