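Package: diagSNP
Title: Species-Diagnostic SNP Panel Design from Pooled Whole-Genome
    Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of species-diagnostic genomic
    variants from pooled whole-genome sequencing of closely related
    taxa, developed around a four-species parasitoid wasp panel
    (Palmistichus elaeisis, Tetrastichus howardi, Trichospilus
    diatraeae, Trichogramma pretiosum). Implements read quality rules,
    a variant-retention cascade over multi-sample VCFs (biallelic SNV,
    depth, fixed-site, flanking-sequence and call-rate filters),
    reference-genome evaluation via shared-interval statistics,
    PCA-loading marker ranking, species-specific and pairwise
    diagnostic allele-frequency rules, in-silico pure and admixed
    sample simulation, SVM species assignment, and probe flank
    extraction. Ships a synthetic scenario generator with truth tables
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
biocViews: SNP, VariantDetection, Classification, Sequencing
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
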