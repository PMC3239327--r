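Package: tfclusters
Title: Mapping Regulatory Elements from Multi-Factor ChIP-Seq Peak Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate regulatory elements as clusters of
    co-localised transcription factor ChIP-Seq peaks, compares cluster
    statistics against a within-chromosome shuffle null, annotates clusters
    with gene context (promoter, gene body, intergenic) and expression
    class, classifies clusters as transcript-associated or enhancer-like
    from histone-modification and RNA-polymerase domains, and quantifies
    factor composition, chromatin-mark redundancy and promoter coverage
    saturation.  Ships a synthetic-genome generator with a ground-truth
    manifest so the whole pipeline can be exercised end-to-end with
    recoverable planted elements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    igraph,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
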