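Package: hzscan
Title: Viability-Selection and Structural-Variant Scans for Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting extrinsic postzygotic selection in admixed
    cohorts sampled from a hybrid zone. Provides ancestry-informative-marker
    (AIM) data structures and summaries (genome-wide ancestry, interspecific
    heterozygosity, LD pruning), per-locus binomial GLM scans of interspecific
    heterozygosity across age classes, pairwise ancestry-mismatch scans,
    gene-overlap enrichment with LD-block gene assignment, a structural-variant
    evidence suite (windowed local PCA, MDS outlier regions, cluster
    genotyping, LD contrasts), Hi-C contact-matrix comparison, and a synthetic
    hybrid-zone cohort generator with planted selection and inversion ground
    truth for method validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
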