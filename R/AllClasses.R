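#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom BiocGenerics start end width
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom GenomicAlignments GAlignments
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' FusionTarget: the genomic windows and thresholds that parameterize detection
#'
#' A `FusionTarget` bundles everything the detector needs to know about one
#' fusion: the window of the 5' partner gene (EML4; the gene whose reads are
#' scanned), the window of the 3' partner gene (ALK; where mates must map),
#' and the evidence thresholds. Coordinates are 1-based inclusive throughout,
#' as printed in SAM text. Strand is annotation only; detection never
#' branches on it.
#'
#' @slot name Target identifier, e.g. `"EML4-ALK"`.
#' @slot build Genome build tag, `"hg38"` or `"hg19"`.
#' @slot fivePrime [GenomicRanges::GRanges] of length 1: the 5' gene window.
#' @slot threePrime [GenomicRanges::GRanges] of length 1: the 3' gene window.
#' @slot minPairs Minimum number of read pairs (distinct read identifiers in
#'   the 5' window with mate in the 3' window) for a positive call; default 2.
#' @slot minClipReads Minimum number of soft-clipped junction-spanning reads
#'   for a positive call; default 2.
#' @slot flankLen Number of bases reported on each side of the breakpoint in
#'   the consensus flank sequences; default 20.
#'
#' @seealso [builtinTarget()], [loadTargetConfig()], [detectFusion()]
#' @exportClass FusionTarget
setClass("FusionTarget",
    slots = c(
        name = "character",
        build = "character",
        fivePrime = "GRanges",
        threePrime = "GRanges",
        minPairs = "integer",
        minClipReads = "integer",
        flankLen = "integer"
    )
)

.validGeneRegion <- function(gr, what) {
    if (length(gr) != 1L)
        return(sprintf("%s must be a single genomic window", what))
    if (is.na(GenomicRanges::start(gr)) || is.na(GenomicRanges::end(gr)))
        return(sprintf("%s: start/end must not be NA", what))
    if (GenomicRanges::start(gr) < 1L)
        return(sprintf("%s: start must be >= 1", what))
    if (GenomicRanges::start(gr) > GenomicRanges::end(gr))
        return(sprintf("%s: start must be <= end", what))
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (is.na(chrom) || !nzchar(chrom))
        return(sprintf("%s: chromosome name must be non-empty", what))
    if (is.null(gr$label) || !nzchar(gr$label))
        return(sprintf("%s: gene label must be non-empty", what))
    NULL
}

setValidity("FusionTarget", function(object) {
    msgs <- character()
    for (sl in c("name", "build")) {
        v <- slot(object, sl)
        if (length(v) != 1L || is.na(v) || !nzchar(v))
            msgs <- c(msgs, sprintf("'%s' must be a non-empty string", sl))
    }
    m <- .validGeneRegion(object@fivePrime, "five_prime region")
    if (!is.null(m)) msgs <- c(msgs, m)
    m <- .validGeneRegion(object@threePrime, "three_prime region")
    if (!is.null(m)) msgs <- c(msgs, m)
    if (length(object@minPairs) != 1L || is.na(object@minPairs) ||
        object@minPairs < 1L)
        msgs <- c(msgs, "'min_pairs' must be an integer >= 1")
    if (length(object@minClipReads) != 1L || is.na(object@minClipReads) ||
        object@minClipReads < 1L)
        msgs <- c(msgs, "'min_clip_reads' must be an integer >= 1")
    if (length(object@flankLen) != 1L || is.na(object@flankLen) ||
        object@flankLen < 0L)
        msgs <- c(msgs, "'flank_len' must be an integer >= 0")
    if (length(msgs) == 0L) {
        ov <- GenomicRanges::findOverlaps(object@fivePrime, object@threePrime,
            ignore.strand = TRUE)
        if (length(ov) > 0L)
            msgs <- c(msgs, "five_prime and three_prime regions must not overlap")
    }
    if (length(msgs)) msgs else TRUE
})

#' FusionCall: the detection verdict for one sample
#'
#' Returned by [detectFusion()]. When the sample is negative the evidence
#' GAlignments is empty and the characterization fields (consensus
#' breakpoint, flanks, depth) are `NA`.
#'
#' @slot status `"positive"` or `"negative"`.
#' @slot nPairs Count of distinct read identifiers in the 5' window whose
#'   mate maps inside the 3' window.
#' @slot nClipReads Count of soft-clipped junction-spanning reads among the
#'   mate-filtered candidates.
#' @slot breakpointTable Named integer vector: candidate breakpoint position
#'   (name) to number of supporting clipped reads (value).
#' @slot consensusBreakpoint Modal breakpoint position (ties broken toward
#'   the smallest coordinate), or `NA` when negative.
#' @slot fivePrimeFlank Per-column majority consensus of the aligned bases
#'   ending at the breakpoint (EML4 side), or `NA`.
#' @slot threePrimeFlank Per-column majority consensus of the soft-clipped
#'   bases following the breakpoint (ALK side, as sequenced), or `NA`.
#' @slot breakpointDepth Number of filter-passing reads whose aligned span
#'   covers the consensus breakpoint, or `NA`.
#' @slot evidence [GenomicAlignments::GAlignments] of the supporting
#'   soft-clipped reads with clip annotation in `mcols()`; empty when
#'   negative.
#' @slot target The [FusionTarget] the call was made against.
#'
#' @exportClass FusionCall
setClass("FusionCall",
    slots = c(
        status = "character",
        nPairs = "integer",
        nClipReads = "integer",
        breakpointTable = "integer",
        consensusBreakpoint = "integer",
        fivePrimeFlank = "character",
        threePrimeFlank = "character",
        breakpointDepth = "integer",
        evidence = "GAlignments",
        target = "FusionTarget"
    )
)

setValidity("FusionCall", function(object) {
    msgs <- character()
    if (!object@status %in% c("positive", "negative"))
        msgs <- c(msgs, "status must be 'positive' or 'negative'")
    if (object@status == "negative" && length(object@evidence) > 0L)
        msgs <- c(msgs, "a negative call must carry no evidence reads")
    if (length(object@breakpointTable) &&
        sum(object@breakpointTable) != object@nClipReads)
        msgs <- c(msgs, "breakpoint table counts must sum to nClipReads")
    if (length(msgs)) msgs else TRUE
})

#' SimConfig: parameters of one synthetic cell-free DNA sample
#'
#' Describes a hybridization-capture paired-end sequencing experiment over
#' two synthetic gene windows, optionally harbouring an EML4-ALK-style
#' fusion. Defaults emulate the plasma cfDNA setting: ~165 bp fragments
#' sequenced as 100 bp paired-end reads.
#'
#' @slot seed Integer seed; one pseudo-random stream per sample is fully
#'   determined by it.
#' @slot fivePrimeWindow,threePrimeWindow [GenomicRanges::GRanges] gene
#'   windows (defaults: the built-in EML4-ALK hg38 windows).
#' @slot breakpoint5p,breakpoint3p 1-based fusion breakpoints inside the
#'   respective windows.
#' @slot fusionFragments Number of fusion-derived cfDNA fragments to draw
#'   (0 for a fusion-free sample).
#' @slot wildtypeDepth Mean background read coverage over each window.
#' @slot fragLenMean,fragLenSd Fragment length distribution (bp); default
#'   165 +/- 10.
#' @slot readLen Read length (bp); default 100.
#' @slot errorRate Per-base substitution probability in `[0, 1)`; default 0.
#' @slot minAnchor Minimum aligned bases required to anchor a
#'   junction-spanning read on a side; default 20.
#'
#' @seealso [SimConfig()], [simulateSample()]
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        seed = "integer",
        fivePrimeWindow = "GRanges",
        threePrimeWindow = "GRanges",
        breakpoint5p = "integer",
        breakpoint3p = "integer",
        fusionFragments = "integer",
        wildtypeDepth = "numeric",
        fragLenMean = "numeric",
        fragLenSd = "numeric",
        readLen = "integer",
        errorRate = "numeric",
        minAnchor = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msgs <- character()
    m <- .validGeneRegion(object@fivePrimeWindow, "five_prime window")
    if (!is.null(m)) msgs <- c(msgs, m)
    m <- .validGeneRegion(object@threePrimeWindow, "three_prime window")
    if (!is.null(m)) msgs <- c(msgs, m)
    if (object@errorRate < 0 || object@errorRate >= 1)
        msgs <- c(msgs, "error_rate must lie in [0, 1)")
    if (object@minAnchor < 1L)
        msgs <- c(msgs, "min_anchor must be >= 1")
    if (object@fusionFragments < 0L)
        msgs <- c(msgs, "fusion_fragments must be >= 0")
    if (object@wildtypeDepth < 0)
        msgs <- c(msgs, "wildtype_depth must be >= 0")
    if (object@readLen < 1L)
        msgs <- c(msgs, "read_len must be >= 1")
    if (object@fragLenMean <= 0 || object@fragLenSd < 0)
        msgs <- c(msgs, "fragment length parameters must be positive")
    minw <- 2 * (object@fragLenMean + object@readLen)
    if (length(msgs) == 0L) {
        for (w in c("fivePrimeWindow", "threePrimeWindow")) {
            if (GenomicRanges::width(slot(object, w)) < minw)
                msgs <- c(msgs, sprintf(
                    "%s is too small for simulation: need >= %d bp",
                    w, ceiling(minw)))
        }
        bp5 <- object@breakpoint5p
        bp3 <- object@breakpoint3p
        w5 <- object@fivePrimeWindow
        w3 <- object@threePrimeWindow
        if (bp5 < GenomicRanges::start(w5) || bp5 > GenomicRanges::end(w5))
            msgs <- c(msgs, "breakpoint_5p outside the five_prime window")
        if (bp3 < GenomicRanges::start(w3) || bp3 > GenomicRanges::end(w3))
            msgs <- c(msgs, "breakpoint_3p outside the three_prime window")
        if (object@fusionFragments > 0L) {
            margin <- ceiling(2 * object@fragLenMean + object@readLen)
            if (bp5 - GenomicRanges::start(w5) < margin ||
                bp3 - GenomicRanges::start(w3) < margin)
                msgs <- c(msgs, sprintf(
                    "breakpoints must lie >= %d bp inside their window start for fragment sampling",
                    margin))
        }
    }
    if (length(msgs)) msgs else TRUE
})
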