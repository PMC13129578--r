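Package: svCohort
Title: Cross-Sample Structural Variant Integration, Annotation and
    Genotype Analysis for Long-Read Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates per-sample structural variant (SV) calls from
    long-read callers (Sniffles-dialect VCF) into cohort-level merged
    sites using a positional-offset threshold proportional to the square
    root of SV length, filters low-confidence sites by breakpoint
    dispersion and precision flags, attaches reference flanking
    sequences for marker design, classifies sites against a gene track
    (genic versus upstream regions), and writes reproducible tabular
    outputs. Includes cohort summary statistics (per-chromosome density,
    per-sample zygosity, length histograms, marker-candidate selection,
    genotype concordance), genotype PCA, per-chromosome genotype maps,
    and a fully seeded synthetic-cohort simulator with truth-based
    recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Biostrings,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: StructuralVariation, VariantAnnotation, Sequencing, Genetics
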