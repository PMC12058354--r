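Package: swabdiv
Title: Insect eDNA Metabarcoding from Vegetation Swabs with Nanopore Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for insect environmental DNA (eDNA)
    metabarcoding of vegetation swabs sequenced on nanopore platforms.
    Provides quality and length filtering of demultiplexed amplicon reads,
    batch-based greedy similarity clustering with majority-vote consensus
    building and consensus-level merging, threshold/LCA taxonomic assignment
    from similarity-search hits against lineage-annotated references, and the
    downstream ecological inference: exact sample-based rarefaction,
    nonlinear species-accumulation models with AIC selection, Hill numbers,
    the Jaccard beta-diversity partition into turnover and nestedness,
    PERMANOVA, principal coordinates analysis, and noncentral-F power
    analysis for balanced one-way ANOVA designs. A synthetic-data module
    generates lineage-annotated reference sequences, nanopore-like reads
    with known community ground truth, and habitat-structured site-by-taxon
    matrices for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
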