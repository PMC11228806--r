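Package: tmeco
Title: Segment-Level Spatial Transcriptomics Analysis of Tumor and
    Microenvironment Ecosystems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for NanoString GeoMx digital
    spatial profiler (DSP) segment data of the kind produced by paired
    tumor/microenvironment profiling of small-cell lung cancer: probe-to-gene
    collapse with outlier removal, negative-probe limit of quantification,
    segment quality control, third-quartile (Q3) normalization, highly
    variable gene selection, elbow-based k-means phenotype clustering with
    principal-component contribution signatures, single-sample gene set
    enrichment (ssGSEA), neuroendocrine scoring, tumor purity modeling,
    Shannon diversity, simplex-constrained cell-type deconvolution,
    ligand-receptor communication scoring, preranked GSEA, and quantile-based
    survival stratification (Kaplan-Meier, log-rank, Cox). A synthetic-data
    generator with planted ground truth emulates the GeoMx cohort structure
    so that every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    fgsea
Config/testthat/edition: 3
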