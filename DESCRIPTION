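Package: t3enhancers
Title: Classification of Thyroid-Hormone-Responsive Enhancers from
    ChIP-seq, Hi-C and RNA-seq Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for classifying triiodothyronine
    (T3)-responsive enhancers from multi-factor ChIP-seq, Hi-C and RNA-seq
    count data. Calls regions hyperacetylated at both H3K27 and H3K9 with a
    negative-binomial differential test, classifies thyroid-hormone-receptor
    binding sites into poised (type 1A) and T3-established (type 1B) classes
    by HDAC3 occupancy tertiles, explains TR-independent hyperacetylation
    through super-enhancer co-occupancy, TAD confinement and Hi-C contacts
    against an opposite-direction background, and links hyperacetylated
    regions to differentially expressed genes within 100 kb of the TSS with
    random-gene enrichment nulls. Ships a truth-labelled synthetic data
    generator so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    yaml,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
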