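Package: antisenseq
Title: Strand-Aware Detection and Quantification of Antisense Transcription
    from Stranded RNA-Seq
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies antisense transcription units from stranded
    (dUTP-protocol) RNA-seq alignments. Reads are classified against a gene
    annotation as sense, antisense, intergenic or ambiguous using the
    library-protocol strand rule; antisense and intergenic reads are
    assembled reference-free into transcription units by strand-aware
    interval merging; units and sense genes are quantified per sample and
    tested for differential expression between conditions with a
    negative-binomial exact test; antisense units are associated with their
    overlapping opposite-strand sense genes and cross-tabulated against
    sense-gene regulation; gene-set overlaps and hypergeometric
    over-representation complete the analysis. A negative-binomial read
    simulator with a truth table makes the whole pipeline testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    BiocGenerics,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
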