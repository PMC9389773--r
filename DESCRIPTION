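Package: relapseScope
Title: Clonal and Transcriptional Dynamics of Paired Diagnosis-Relapse
    AML Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for paired diagnosis (Dx) and relapse (Re)
    acute myeloid leukemia samples profiled by plate-based single-cell
    RNA-seq (SORT-seq/CEL-Seq2) and exome sequencing. Provides per-cell
    UMI quality control with spike-in and mitochondrial gates,
    library-size log-normalization, Fisher-exact testing of variant
    allele frequency shifts between timepoints with Benjamini-Hochberg
    correction, inferred copy-number (iCNV) analysis in fixed genomic
    tiles with B-allele-fraction confirmation at heterozygous SNPs,
    LSC17 leukemic stem cell and cell-cycle signature scoring, Wilcoxon
    marker gene detection, and a seeded synthetic Dx/Re data generator
    with planted ground truth that makes every stage testable without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
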