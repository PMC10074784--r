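.normChrom <- function(x) sub("^chr", "", as.character(x))

#' Keep 5'-window reads whose mate maps inside the 3' window
#'
#' Implements the discordant mate filter: of the reads overlapping the 5'
#' partner window, only those whose mate chromosome equals the 3' partner
#' chromosome (dialect-insensitively) and whose mate position lies inside
#' the 3' window (1-based inclusive on both bounds) are candidate fusion
#' reads. The pair count `nPairs` is the number of distinct read
#' identifiers among them.
#'
#' @param reads A `GAlignments` from [streamRegionReads()] over the 5'
#'   window.
#' @param target A [FusionTarget].
#' @return The kept subset of `reads` (possibly empty), with the distinct
#'   read-identifier count in `metadata(mcols())` exposed via [nPairs()]
#'   after [detectFusion()]; use `length(unique(mcols(x)$qname))` directly
#'   on the return value.
#' @export
selectMatePairs <- function(reads, target) {
    stopifnot(is(reads, "GAlignments"), is(target, "FusionTarget"))
    if (length(reads) == 0L)
        return(reads)
    tp <- target@threePrime
    m <- S4Vectors::mcols(reads)
    keep <- !is.na(m$mpos) & !is.na(m$mrnm) &
        .normChrom(m$mrnm) == .normChrom(GenomicRanges::seqnames(tp)) &
        m$mpos >= GenomicRanges::start(tp) &
        m$mpos <= GenomicRanges::end(tp)
    reads[keep]
}

## Soft-clip geometry of one CIGAR: lengths of the terminal S operations.
## Hard clips may sit outside soft clips per the SAM ordering rules.
.terminalClips <- function(cigar) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
    left <- vapply(seq_along(ops), function(i) {
        o <- ops[[i]]; l <- lens[[i]]
        j <- if (o[1L] == "H" && length(o) > 1L) 2L else 1L
        if (o[j] == "S") l[j] else 0L
    }, integer(1))
    right <- vapply(seq_along(ops), function(i) {
        o <- ops[[i]]; l <- lens[[i]]; n <- length(o)
        j <- if (o[n] == "H" && n > 1L) n - 1L else n
        if (o[j] == "S") l[j] else 0L
    }, integer(1))
    list(left = left, right = right)
}

#' Extract soft-clip junction evidence from candidate reads
#'
#' A candidate read contributes evidence when its CIGAR contains an `"S"`
#' operation. The used clip is the longer of the two read ends (ties go to
#' the right end, where junction clips sit in the canonical EML4-ALK
#' geometry). The putative breakpoint is the reference coordinate of the
#' aligned base adjacent to the used clip: for a right-end clip
#' `pos + reference_width - 1`, for a left-end clip `pos`. Evidence whose
#' breakpoint falls outside the 5' window is discarded.
#'
#' @param candidates A `GAlignments` from [selectMatePairs()].
#' @param target A [FusionTarget].
#' @return A `GAlignments` subset with additional metadata columns
#'   `clipEnd` (`"left"`/`"right"`), `clipLen`, `breakpoint`, `clippedSeq`
#'   (the soft-clipped bases as sequenced; the 3'-gene side) and
#'   `alignedRef` (the aligned bases laid out in reference space, with
#'   `-`/`.` at deletion/skip gaps; the 5'-gene side).
#' @export
identifySoftclips <- function(candidates, target) {
    stopifnot(is(candidates, "GAlignments"), is(target, "FusionTarget"))
    cg <- GenomicAlignments::cigar(candidates)
    clipped <- hasSoftclip(cg)
    ev <- candidates[clipped]
    if (length(ev) == 0L) {
        S4Vectors::mcols(ev)$clipEnd <- character(0)
        S4Vectors::mcols(ev)$clipLen <- integer(0)
        S4Vectors::mcols(ev)$breakpoint <- integer(0)
        S4Vectors::mcols(ev)$clippedSeq <- character(0)
        S4Vectors::mcols(ev)$alignedRef <- character(0)
        return(ev)
    }
    cg <- GenomicAlignments::cigar(ev)
    clips <- .terminalClips(cg)
    useRight <- clips$right >= clips$left  # longer clip; ties -> right end
    clipLen <- ifelse(useRight, clips$right, clips$left)
    breakpoint <- as.integer(ifelse(useRight,
        GenomicRanges::end(ev), GenomicRanges::start(ev)))
    seqs <- S4Vectors::mcols(ev)$seq
    seqsChr <- as.character(seqs)
    qlen <- nchar(seqsChr)
    clippedSeq <- character(length(ev))
    clippedSeq[useRight] <- substring(seqsChr[useRight],
        qlen[useRight] - clipLen[useRight] + 1L, qlen[useRight])
    clippedSeq[!useRight] <- substring(seqsChr[!useRight], 1L,
        clipLen[!useRight])
    alignedRef <- as.character(GenomicAlignments::sequenceLayer(
        seqs, cg, from = "query", to = "reference"))
    S4Vectors::mcols(ev)$clipEnd <- ifelse(useRight, "right", "left")
    S4Vectors::mcols(ev)$clipLen <- as.integer(clipLen)
    S4Vectors::mcols(ev)$breakpoint <- breakpoint
    S4Vectors::mcols(ev)$clippedSeq <- clippedSeq
    S4Vectors::mcols(ev)$alignedRef <- alignedRef
    fp <- target@fivePrime
    inWin <- breakpoint >= GenomicRanges::start(fp) &
        breakpoint <= GenomicRanges::end(fp)
    ev[inWin]
}

#' Tally candidate breakpoints and pick the consensus
#'
#' The breakpoint table maps each observed breakpoint position to the
#' number of supporting clipped reads; the consensus is the modal position,
#' with ties broken deterministically toward the smallest coordinate.
#'
#' @param evidence A non-empty `GAlignments` from [identifySoftclips()].
#' @return A list with `table` (named integer vector, positions in
#'   ascending order) and `consensus` (integer position).
#' @export
inferBreakpoint <- function(evidence) {
    if (!is(evidence, "GAlignments") || length(evidence) == 0L)
        stop("no junction-spanning reads: cannot infer a breakpoint")
    bp <- S4Vectors::mcols(evidence)$breakpoint
    tab <- table(bp)
    counts <- as.integer(tab)
    pos <- as.integer(names(tab))  # table() sorts positions ascending
    names(counts) <- pos
    consensus <- pos[which.max(counts)]  # first max = smallest position
    list(table = counts, consensus = as.integer(consensus))
}

.majorityBase <- function(votes) {
    votes <- votes[votes %in% c("A", "C", "G", "T")]
    if (length(votes) == 0L)
        return("N")
    tab <- sort(table(votes), decreasing = TRUE)
    if (length(tab) > 1L && tab[[1L]] == tab[[2L]])
        return("N")  # tied column
    names(tab)[[1L]]
}

#' Consensus sequence leading up to the breakpoint (5' gene side)
#'
#' Builds the per-column majority consensus of the aligned read bases over
#' the reference interval `[consensus - flankLen + 1, consensus]`, using
#' only evidence reads whose breakpoint equals the consensus. Columns with
#' no coverage or a tied vote emit `'N'` (never IUPAC ambiguity codes, so
#' the output stays primer-design-ready).
#'
#' @param evidence A `GAlignments` from [identifySoftclips()].
#' @param consensus Consensus breakpoint position (see [inferBreakpoint()]).
#' @param flankLen Number of bases to report; `0` yields `""`.
#' @return A character string of length `flankLen`.
#' @export
fivePrimeFlank <- function(evidence, consensus, flankLen) {
    flankLen <- .asCount(flankLen, "flank_len")
    if (flankLen == 0L)
        return("")
    ev <- evidence[S4Vectors::mcols(evidence)$breakpoint == consensus]
    positions <- seq(consensus - flankLen + 1L, consensus)
    starts <- GenomicRanges::start(ev)
    refs <- S4Vectors::mcols(ev)$alignedRef
    out <- vapply(positions, function(p) {
        off <- p - starts + 1L
        ok <- off >= 1L & off <= nchar(refs)
        .majorityBase(substring(refs[ok], off[ok], off[ok]))
    }, character(1))
    paste(out, collapse = "")
}

#' Consensus sequence following the breakpoint (3' gene side)
#'
#' Builds the per-column majority consensus of the soft-clipped bases of
#' the consensus-supporting evidence reads, walking away from the junction
#' (for a right-end clip the clipped bases as stored; for a left-end clip
#' the junction-adjacent base is the last clipped base, so the clip is read
#' in reverse). Bases are reported as sequenced, without projecting onto
#' the 3' gene's annotated strand (EML4 and ALK lie on opposite strands;
#' see the package vignette). The output is truncated at
#' `min(flankLen, longest clip)`; columns beyond a given clip's length
#' simply do not receive its vote.
#'
#' @inheritParams fivePrimeFlank
#' @return A character string of length `min(flankLen, longest clip)`.
#' @export
threePrimeFlank <- function(evidence, consensus, flankLen) {
    flankLen <- .asCount(flankLen, "flank_len")
    if (flankLen == 0L)
        return("")
    ev <- evidence[S4Vectors::mcols(evidence)$breakpoint == consensus]
    if (length(ev) == 0L)
        return("")
    m <- S4Vectors::mcols(ev)
    clips <- ifelse(m$clipEnd == "right", m$clippedSeq,
        vapply(m$clippedSeq, .revString, character(1), USE.NAMES = FALSE))
    width <- min(flankLen, max(nchar(clips)))
    out <- vapply(seq_len(width), function(i) {
        ok <- nchar(clips) >= i
        .majorityBase(substring(clips[ok], i, i))
    }, character(1))
    paste(out, collapse = "")
}

.revString <- function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Read depth at the breakpoint
#'
#' Counts the filter-passing records whose aligned reference span covers
#' the consensus breakpoint position. A position inside a deletion (`D`)
#' counts as covered; a position inside an intron-style skip (`N`) does
#' not. The breakpoint read depth serves as a surrogate for the
#' circulating-tumor-DNA load of the sample.
#'
#' @param bam Path to the indexed BAM.
#' @param target A [FusionTarget]; the breakpoint lies on its 5' window
#'   chromosome.
#' @param consensus Consensus breakpoint position.
#' @inheritParams streamRegionReads
#' @return Integer read count.
#' @export
breakpointDepth <- function(bam, target, consensus, minMapq = NA_integer_,
                            flag = .defaultFlagFilter()) {
    if (is.null(consensus) || length(consensus) != 1L || is.na(consensus))
        stop("breakpoint depth requires a consensus breakpoint position")
    fp <- target@fivePrime
    site <- geneRegion(as.character(GenomicRanges::seqnames(fp)),
        consensus, consensus, label = fp$label)
    reads <- streamRegionReads(bam, site, minMapq = minMapq, flag = flag)
    if (length(reads) == 0L)
        return(0L)
    spans <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        GenomicAlignments::cigar(reads),
        pos = GenomicRanges::start(reads),
        ops = c("M", "D", "=", "X"))
    covered <- vapply(seq_along(spans), function(i) {
        r <- spans[[i]]
        any(BiocGenerics::start(r) <= consensus &
            BiocGenerics::end(r) >= consensus)
    }, logical(1))
    sum(covered)
}

#' Detect an EML4-ALK-style gene fusion in a BAM file
#'
#' The full detection procedure: (1) stream filter-passing reads
#' overlapping the 5' partner window; (2) keep those whose mate maps inside
#' the 3' partner window (`nPairs` = distinct read identifiers kept);
#' (3) among them, identify soft-clipped junction-spanning reads
#' (`nClipReads`). The sample is called positive exactly when
#' `nPairs >= minPairs(target)` and `nClipReads >= minClipReads(target)`.
#' A positive call is characterized further: the breakpoint table and
#' consensus breakpoint, the consensus sequences flanking the junction on
#' both gene sides, and the read depth at the breakpoint. A negative call
#' carries an empty evidence set and `NA` characterization fields; a
#' fusion-free input is never an error.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM from
#'   hybridization-capture paired-end sequencing.
#' @param target A [FusionTarget]; default the built-in EML4-ALK hg38
#'   configuration.
#' @inheritParams streamRegionReads
#' @return A [FusionCall].
#' @examples
#' cfg <- SimConfig(seed = 7L, fusionFragments = 60L, wildtypeDepth = 30,
#'     fivePrimeWindow = geneRegion("chr2", 1e6, 1e6 + 4999, label = "EML4"),
#'     threePrimeWindow = geneRegion("chr2", 2e6, 2e6 + 4999, label = "ALK"))
#' sim <- simulateSample(cfg, file.path(tempdir(), "ex"))
#' detectFusion(sim$bam, simTarget(cfg))
#' @export
detectFusion <- function(bam, target = builtinTarget("EML4-ALK", "hg38"),
                         minMapq = NA_integer_) {
    stopifnot(is(target, "FusionTarget"))
    reads <- streamRegionReads(bam, target@fivePrime, minMapq = minMapq)
    pairs <- selectMatePairs(reads, target)
    nPairs <- length(unique(S4Vectors::mcols(pairs)$qname))
    evidence <- identifySoftclips(pairs, target)
    nClip <- length(evidence)
    positive <- nPairs >= target@minPairs && nClip >= target@minClipReads
    if (!positive) {
        return(new("FusionCall", status = "negative",
            nPairs = as.integer(nPairs), nClipReads = as.integer(nClip),
            breakpointTable = integer(0),
            consensusBreakpoint = NA_integer_,
            fivePrimeFlank = NA_character_, threePrimeFlank = NA_character_,
            breakpointDepth = NA_integer_,
            evidence = evidence[0], target = target))
    }
    bp <- inferBreakpoint(evidence)
    new("FusionCall", status = "positive",
        nPairs = as.integer(nPairs), nClipReads = as.integer(nClip),
        breakpointTable = bp$table,
        consensusBreakpoint = bp$consensus,
        fivePrimeFlank = fivePrimeFlank(evidence, bp$consensus,
            target@flankLen),
        threePrimeFlank = threePrimeFlank(evidence, bp$consensus,
            target@flankLen),
        breakpointDepth = as.integer(breakpointDepth(bam, target,
            bp$consensus, minMapq = minMapq)),
        evidence = evidence, target = target)
}

#' @describeIn FusionCall-class `"positive"` or `"negative"`.
#' @param x A `FusionCall`.
#' @export
fusionStatus <- function(x) x@status

#' @describeIn FusionCall-class Distinct 5'-window read identifiers with
#'   mate in the 3' window.
#' @export
nPairs <- function(x) x@nPairs

#' @describeIn FusionCall-class Number of soft-clipped junction reads.
#' @export
nClipReads <- function(x) x@nClipReads

#' @describeIn FusionCall-class Breakpoint position to supporting-read
#'   count.
#' @export
breakpointTable <- function(x) x@breakpointTable

#' @describeIn FusionCall-class Modal breakpoint (`NA` when negative).
#' @export
consensusBreakpoint <- function(x) x@consensusBreakpoint

#' @describeIn FusionCall-class Named character vector with elements
#'   `five_prime` and `three_prime` (`NA` when negative).
#' @export
flankSequences <- function(x) {
    c(five_prime = x@fivePrimeFlank, three_prime = x@threePrimeFlank)
}

#' @describeIn FusionCall-class Read depth at the consensus breakpoint
#'   (`NA` when negative).
#' @export
breakpointReadDepth <- function(x) x@breakpointDepth

#' @describeIn FusionCall-class The supporting reads as a `GAlignments`
#'   (empty when negative).
#' @export
evidenceReads <- function(x) x@evidence

#' @describeIn FusionCall-class The [FusionTarget] used for the call.
#' @export
callTarget <- function(x) x@target

setMethod("show", "FusionCall", function(object) {
    cat(sprintf("FusionCall [%s, %s]: %s\n", object@target@name,
        object@target@build, toupper(object@status)))
    cat(sprintf("  mate pairs: %d (min %d); clipped reads: %d (min %d)\n",
        object@nPairs, object@target@minPairs, object@nClipReads,
        object@target@minClipReads))
    if (object@status == "positive") {
        cat(sprintf("  consensus breakpoint: %s:%s  (depth %d)\n",
            as.character(GenomicRanges::seqnames(object@target@fivePrime)),
            format(object@consensusBreakpoint, big.mark = ","),
            object@breakpointDepth))
        cat("  breakpoint table:",
            paste(sprintf("%s=%d", names(object@breakpointTable),
                object@breakpointTable), collapse = " "), "\n")
        cat("  5' flank:", object@fivePrimeFlank, "\n")
        cat("  3' flank:", object@threePrimeFlank, "\n")
    }
})

#' Write a machine-readable fusion report
#'
#' Serializes a [FusionCall] as JSON (schema: `status`, `n_pairs`,
#' `n_clip_reads`, `breakpoint_table`, `consensus_breakpoint`,
#' `eml4_flank`, `alk_flank`, `breakpoint_depth`, `target`, `evidence`).
#' Absent characterization fields are written as JSON `null`.
#'
#' @param call A [FusionCall].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeFusionReport <- function(call, path) {
    stopifnot(is(call, "FusionCall"))
    m <- S4Vectors::mcols(call@evidence)
    positive <- call@status == "positive"
    x <- list(
        status = call@status,
        n_pairs = call@nPairs,
        n_clip_reads = call@nClipReads,
        breakpoint_table = if (positive)
            as.list(stats::setNames(as.integer(call@breakpointTable),
                names(call@breakpointTable))) else
            stats::setNames(list(), character(0)),
        consensus_breakpoint = if (positive) call@consensusBreakpoint else NULL,
        eml4_flank = if (positive) call@fivePrimeFlank else NULL,
        alk_flank = if (positive) call@threePrimeFlank else NULL,
        breakpoint_depth = if (positive) call@breakpointDepth else NULL,
        clip_orientation_note = paste("alk_flank bases are reported as",
            "sequenced (not projected onto the ALK annotated strand;",
            "EML4 and ALK lie on opposite strands)"),
        target = list(name = call@target@name, build = call@target@build,
            five_prime = .regionToList(call@target@fivePrime),
            three_prime = .regionToList(call@target@threePrime),
            min_pairs = call@target@minPairs,
            min_clip_reads = call@target@minClipReads,
            flank_len = call@target@flankLen),
        evidence = if (length(call@evidence)) lapply(
            seq_along(call@evidence), function(i) list(
                qname = m$qname[i],
                pos = GenomicRanges::start(call@evidence)[i],
                cigar = GenomicAlignments::cigar(call@evidence)[i],
                clip_end = m$clipEnd[i],
                clip_len = m$clipLen[i],
                breakpoint = m$breakpoint[i])) else list())
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
        null = "null")
    invisible(path)
}

#' One-line cohort summary of a fusion call
#'
#' @param call A [FusionCall].
#' @param sampleId Sample identifier for the `sample` column.
#' @return A one-row `data.frame` suitable for TSV concatenation across a
#'   cohort.
#' @export
fusionSummaryRow <- function(call, sampleId) {
    data.frame(sample = sampleId, status = call@status,
        n_pairs = call@nPairs, n_clip_reads = call@nClipReads,
        consensus_breakpoint = call@consensusBreakpoint,
        breakpoint_depth = call@breakpointDepth,
        eml4_flank = call@fivePrimeFlank, alk_flank = call@threePrimeFlank,
        stringsAsFactors = FALSE)
}
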