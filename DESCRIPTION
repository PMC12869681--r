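Package: svcohort
Title: Structural-Variant Cohort Harmonization, QC and Case-Control Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for harmonizing per-sample sequence-resolved structural
    variant (SV) call sets into an analysis-ready cohort and testing SVs for
    disease association. Covers VCF ingestion with length and PASS filters,
    inversion detection by reverse-complement allele similarity, pairwise call
    comparison by sequence and size similarity, greedy cross-sample collapsing,
    technical-replicate concordance and quality-score threshold calibration,
    sample and study outlier screening, known-SV catalog intersection, gene
    annotation, genotype PCA with MAF/HWE/LD filters, two-locus EM linkage
    disequilibrium, single-variant logistic association with Stouffer
    meta-analysis, and gene-based rare-variant burden/SKAT hybrid tests. A
    synthetic-cohort generator with full ground truth supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    cluster,
    rtracklayer
Config/testthat/edition: 3
biocViews: StructuralVariation, VariantAnnotation, GenomeWideAssociation,
    QualityControl, Genetics
RoxygenNote: 7.3.3
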