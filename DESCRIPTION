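Package: shoreMeth
Title: Subtype-Specific CpG Island Shore Methylation and CpG Mutation
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated desk-scale analysis of subtype-structured DNA
    methylation from affinity-capture (MBDCap-seq style) 100-bp bin
    relative methylation scores. Derives CpG island shore and shelf
    annotation, calls differentially methylated bins and regions between
    tumour subtypes with Welch t-tests and Bonferroni control, computes
    island-relative methylation meta-profiles with position-wise ANOVA,
    couples transcription-factor binding site methylation in promoter
    shore overlaps to downstream gene expression via Kruskal-Wallis and
    Spearman screens, stratifies CpG mutation rates by methylation level
    with a binomial mutation caller, classifies subtype-specific
    mutations, and measures cross-technology concordance against
    bisulfite-style per-CpG calls in 2-kb windows. Ships a deterministic
    synthetic-data generator that emulates the subtype structure of a
    three-subtype breast cancer cell line panel so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
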