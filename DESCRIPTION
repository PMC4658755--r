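Package: dfprint
Title: Differential DNase-Seq Footprinting from Strand-Specific Cleavage Imbalance
Version: 0.1.0
Authors@R: person("dfprint", "developers", email = "dfprint@example.org",
    role = c("aut", "cre"))
Description: Detects transcription factor footprints in DNase-seq data from the
    strand-specific imbalance of 5' cleavage events, and scores differential
    occupancy between two DNase-seq datasets with a shuffle-based bootstrap
    percentile test. Includes read-count based differential hypersensitive-site
    scoring, hexamer cleavage-bias corrected average cleavage profiles,
    relative motif-frequency matrices with hierarchical clustering, shared-DHS
    overlap summaries, and a synthetic-data generator that plants footprints
    with known truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
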