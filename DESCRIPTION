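Package: ClipFusion
Title: Soft-Clip Based Detection of EML4-ALK Gene Fusions in Liquid Biopsy Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects EML4-ALK gene fusions in BAM files from hybridization
    capture paired-end sequencing of cell-free DNA. Reads aligned inside the
    EML4 window whose mate maps inside the ALK window are collected, and
    soft-clipped reads among them are used to locate the genomic breakpoint,
    derive consensus sequences flanking the junction on both the EML4 and ALK
    side, and measure the read depth at the breakpoint as a surrogate for
    circulating tumor DNA burden. Ships a ground-truthed cell-free DNA read
    simulator that emits coordinate-sorted indexed BAM files with junction
    spanning soft-clipped reads, exact Fisher statistics for comparing
    detection methods across cohorts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, Sequencing, GeneFusionDetection, StructuralVariation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
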