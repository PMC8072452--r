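Package: peakgene
Title: Integration of ChIP-Seq Binding Sites with Differential Expression Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for consolidating transcription-factor ChIP-Seq binding
    sites with RNA-Seq differential-expression results. Peaks are annotated
    by distance to the nearest gene transcription start site and classified
    as gene-proximal or gene-distal; differentially expressed genes are
    grouped into expression-pattern clusters; per-cluster enrichment of
    TSS-proximal binding is quantified against random-gene and random-site
    null groups with Fisher exact tests; summit-centered tag-density
    profiles, region intensities with Mann-Whitney knockout-versus-wild-type
    comparisons, and cross-dataset Spearman co-localization matrices are
    computed from binned coverage tracks. A seeded synthetic-data generator
    with planted proximity, association, and signal structure supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
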