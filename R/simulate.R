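#' Construct a simulation configuration
#'
#' Builds and validates a [SimConfig]. Defaults emulate the plasma cfDNA
#' capture-sequencing setting the detector targets: ~165 bp fragments
#' (sd 10), 100 bp paired-end reads, error-free bases, and the built-in
#' EML4-ALK hg38 gene windows. Breakpoints default to canonical intronic
#' positions for the built-in windows and to the window midpoints for
#' custom windows.
#'
#' @param seed Integer seed; the whole sample is a deterministic function
#'   of it.
#' @param fivePrimeWindow,threePrimeWindow Length-1 `GRanges`
#'   ([geneRegion()]); each must be at least
#'   `2 * (fragLenMean + readLen)` wide.
#' @param breakpoint5p,breakpoint3p Fusion breakpoints (1-based) inside
#'   the windows; the junction joins the 5' window up to `breakpoint5p`
#'   with the reverse complement of the 3' window up to `breakpoint3p`
#'   (the EML4/ALK opposite-strand inversion).
#' @param fusionFragments Number of fusion-derived fragments (0 = fusion
#'   free).
#' @param wildtypeDepth Mean background read coverage per window.
#' @param fragLenMean,fragLenSd Fragment length normal distribution (bp),
#'   truncated at `[readLen/2, 2 * fragLenMean]`.
#' @param readLen Read length (bp).
#' @param errorRate Per-base substitution probability in `[0, 1)`.
#' @param minAnchor Minimum aligned bases needed to anchor a
#'   junction-spanning read on a side (approximates real aligner
#'   behaviour).
#' @return A validated [SimConfig].
#' @export
SimConfig <- function(seed = 1L,
                      fivePrimeWindow = fivePrimeRegion(
                          builtinTarget("EML4-ALK", "hg38")),
                      threePrimeWindow = threePrimeRegion(
                          builtinTarget("EML4-ALK", "hg38")),
                      breakpoint5p = NULL, breakpoint3p = NULL,
                      fusionFragments = 50L, wildtypeDepth = 100,
                      fragLenMean = 165, fragLenSd = 10,
                      readLen = 100L, errorRate = 0, minAnchor = 20L) {
    mid <- function(gr) as.integer(GenomicRanges::start(gr) +
        GenomicRanges::width(gr) %/% 2L)
    if (is.null(breakpoint5p))
        breakpoint5p <- mid(fivePrimeWindow)
    if (is.null(breakpoint3p))
        breakpoint3p <- mid(threePrimeWindow)
    new("SimConfig", seed = .asCount(seed, "seed"),
        fivePrimeWindow = fivePrimeWindow,
        threePrimeWindow = threePrimeWindow,
        breakpoint5p = .asCount(breakpoint5p, "breakpoint_5p"),
        breakpoint3p = .asCount(breakpoint3p, "breakpoint_3p"),
        fusionFragments = .asCount(fusionFragments, "fusion_fragments"),
        wildtypeDepth = as.numeric(wildtypeDepth),
        fragLenMean = as.numeric(fragLenMean),
        fragLenSd = as.numeric(fragLenSd),
        readLen = .asCount(readLen, "read_len"),
        errorRate = as.numeric(errorRate),
        minAnchor = .asCount(minAnchor, "min_anchor"))
}

#' Fusion target matching a simulation's windows
#'
#' Convenience for detecting on simulated data: a [FusionTarget] whose 5'
#' and 3' windows are the simulation windows, with default thresholds.
#'
#' @param config A [SimConfig].
#' @param ... Passed to [FusionTarget()] (e.g. `minClipReads`).
#' @return A [FusionTarget].
#' @export
simTarget <- function(config, ...) {
    stopifnot(is(config, "SimConfig"))
    FusionTarget("simulated", "synthetic",
        fivePrime = config@fivePrimeWindow,
        threePrime = config@threePrimeWindow, ...)
}

#' Synthetic reference sequences for the two gene windows
#'
#' Uniformly random A/C/G/T sequences matching the configured window
#' widths, reproducible from the seed. These stand in for the real gene
#' sequences; they are labelled synthetic wherever written.
#'
#' @param config A [SimConfig].
#' @return A named [Biostrings::DNAStringSet] of length 2 (names: the
#'   window gene labels).
#' @export
synthReferences <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n,
        replace = TRUE), collapse = "")
    refs <- Biostrings::DNAStringSet(c(
        mk(GenomicRanges::width(config@fivePrimeWindow)),
        mk(GenomicRanges::width(config@threePrimeWindow))))
    names(refs) <- c(config@fivePrimeWindow$label,
        config@threePrimeWindow$label)
    refs
}

.revcompChr <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the fusion contig model
#'
#' The junction template is the 5' window sequence up to `breakpoint5p`
#' followed by the reverse complement of the 3' window sequence up to
#' `breakpoint3p`, modeling the opposite-strand EML4/ALK inversion:
#' template offset `J` (the junction offset) maps to `breakpoint5p`,
#' offset `J + k` maps to `breakpoint3p - k + 1` on the 3' window with
#' complemented bases.
#'
#' @param config A [SimConfig].
#' @param refs Optional `DNAStringSet` from [synthReferences()]; generated
#'   from the seed when omitted.
#' @return A list with `seq` (template as a character string), `junction`
#'   (offset of the last 5'-derived base), `len5`, `len3`, and
#'   `toGenome(offset)`, a vectorized coordinate map returning a
#'   `data.frame` with columns `gene` (`"five_prime"`/`"three_prime"`) and
#'   `pos`.
#' @export
makeFusionTemplate <- function(config, refs = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (is.null(refs))
        refs <- synthReferences(config)
    w5 <- config@fivePrimeWindow
    w3 <- config@threePrimeWindow
    len5 <- config@breakpoint5p - GenomicRanges::start(w5) + 1L
    len3 <- config@breakpoint3p - GenomicRanges::start(w3) + 1L
    if (len5 < 1L || len5 > GenomicRanges::width(w5))
        stop("breakpoint_5p lies outside the five_prime window")
    if (len3 < 1L || len3 > GenomicRanges::width(w3))
        stop("breakpoint_3p lies outside the three_prime window")
    e <- as.character(refs[[1L]])
    a <- as.character(refs[[2L]])
    tmplSeq <- paste0(substring(e, 1L, len5),
        .revcompChr(substring(a, 1L, len3)))
    start5 <- GenomicRanges::start(w5)
    bp3 <- config@breakpoint3p
    toGenome <- function(offset) {
        five <- offset <= len5
        data.frame(
            gene = ifelse(five, "five_prime", "three_prime"),
            pos = as.integer(ifelse(five, start5 + offset - 1L,
                bp3 - (offset - len5) + 1L)),
            stringsAsFactors = FALSE)
    }
    list(seq = tmplSeq, junction = len5, len5 = len5, len3 = len3,
        toGenome = toGenome)
}

.truncLen <- function(n, config) {
    lo <- as.integer(ceiling(config@readLen / 2))
    hi <- as.integer(2 * config@fragLenMean)
    len <- as.integer(round(stats::rnorm(n, config@fragLenMean,
        config@fragLenSd)))
    pmin(pmax(len, lo), hi)
}

#' Draw cfDNA fragment intervals
#'
#' Fusion fragments: midpoints uniform over the junction-centered span of
#' width `2 * fragLenMean`, so the expected fraction spanning the junction
#' is known; lengths are truncated-normal (`fragLenMean`, `fragLenSd`).
#' Wild-type fragments are placed uniformly over each window at a count
#' chosen to reach `wildtypeDepth` sequenced-base coverage in expectation
#' (`width * depth / (2 * readLen)` fragments). Consumes the current RNG
#' stream; call after `set.seed()` (done by [simulateSample()]).
#'
#' @param config A [SimConfig].
#' @return A `data.frame` with columns `kind`
#'   (`"fusion"`/`"wt5"`/`"wt3"`), `start` and `len`; `start` is a
#'   template offset for fusion fragments and a window offset otherwise.
#' @export
sampleFragments <- function(config) {
    stopifnot(is(config, "SimConfig"))
    out <- list()
    nf <- config@fusionFragments
    if (nf > 0L) {
        j <- config@breakpoint5p -
            GenomicRanges::start(config@fivePrimeWindow) + 1L
        mids <- as.integer(round(stats::runif(nf, j - config@fragLenMean,
            j + config@fragLenMean)))
        lens <- .truncLen(nf, config)
        out$fusion <- data.frame(kind = "fusion",
            start = mids - lens %/% 2L, len = lens,
            stringsAsFactors = FALSE)
    }
    for (kind in c("wt5", "wt3")) {
        w <- if (kind == "wt5") config@fivePrimeWindow else
            config@threePrimeWindow
        nw <- as.integer(round(GenomicRanges::width(w) *
            config@wildtypeDepth / (2 * config@readLen)))
        if (nw > 0L) {
            lens <- .truncLen(nw, config)
            starts <- as.integer(floor(stats::runif(nw, 1,
                GenomicRanges::width(w) - lens + 1)))
            out[[kind]] <- data.frame(kind = kind, start = starts,
                len = lens, stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(kind = character(0), start = integer(0),
            len = integer(0), stringsAsFactors = FALSE))
    do.call(rbind, unname(out))
}

## Decide which side anchors a junction-spanning read: a side qualifying
## via minAnchor wins over one that does not; otherwise the longer side
## (ties -> the 5' side).
.anchorFive <- function(len5, len3, minAnchor) {
    q5 <- len5 >= minAnchor
    q3 <- len3 >= minAnchor
    ifelse(q5 == q3, len5 >= len3, q5)
}

#' Oracle alignment of simulated fragments
#'
#' Acts as the simulator's own aligner, removing third-party aligner
#' nondeterminism: each fragment yields two `readLen` bp reads (the
#' fragment's two ends; the second read is sequenced as the reverse
#' complement). A read lying wholly within one gene segment is emitted
#' fully aligned on that gene (orientation and flags follow the segment:
#' the 3' segment is the reverse complement of its window, so its reads
#' align to the reverse strand). A read spanning the junction is anchored
#' on the side with at least `minAnchor` aligned bases (both or neither
#' qualifying: the longer side, ties to the 5' side) and the remainder
#' becomes a terminal soft clip adjacent to the junction.
#'
#' @param fragments A `data.frame` from [sampleFragments()].
#' @param template A list from [makeFusionTemplate()] (may be `NULL` when
#'   no fusion fragments are present).
#' @param config A [SimConfig].
#' @param refs The `DNAStringSet` from [synthReferences()].
#' @return A `data.frame` of SAM fields (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`) plus
#'   annotation columns `junction` (logical: carries a junction soft clip)
#'   and `anchorGene` (`"five_prime"`/`"three_prime"`).
#' @export
oracleAlign <- function(fragments, template, config, refs) {
    stopifnot(is(config, "SimConfig"))
    n <- nrow(fragments)
    if (n == 0L) {
        return(data.frame(qname = character(0), flag = integer(0),
            rname = character(0), pos = integer(0), mapq = integer(0),
            cigar = character(0), rnext = character(0), pnext = integer(0),
            tlen = integer(0), seq = character(0), qual = character(0),
            junction = logical(0), anchorGene = character(0),
            stringsAsFactors = FALSE))
    }
    w5 <- config@fivePrimeWindow
    w3 <- config@threePrimeWindow
    chrom5 <- as.character(GenomicRanges::seqnames(w5))
    chrom3 <- as.character(GenomicRanges::seqnames(w3))
    start5 <- GenomicRanges::start(w5)
    start3 <- GenomicRanges::start(w3)
    bp3 <- config@breakpoint3p
    e <- as.character(refs[[1L]])
    aseq <- as.character(refs[[2L]])
    rl <- config@readLen

    qname <- sprintf("FRAG%06d", seq_len(n))
    fragEnd <- fragments$start + fragments$len - 1L
    readSpan <- pmin(rl, fragments$len)
    ## per-read template/window intervals: read 1 = left fragment end,
    ## read 2 = right fragment end, sequenced as the reverse complement
    reads <- rbind(
        data.frame(frag = seq_len(n), isR2 = FALSE, a = fragments$start,
            b = fragments$start + readSpan - 1L),
        data.frame(frag = seq_len(n), isR2 = TRUE, a = fragEnd - readSpan + 1L,
            b = fragEnd))
    kind <- fragments$kind[reads$frag]
    width <- reads$b - reads$a + 1L
    j <- if (!is.null(template)) template$junction else NA_integer_

    rname <- pos <- seqChr <- cigar <- character(length(kind))
    pos <- integer(length(kind))
    revFlag <- logical(length(kind))
    junction <- logical(length(kind))
    anchorGene <- character(length(kind))

    for (k in c("wt5", "wt3")) {
        idx <- which(kind == k)
        if (!length(idx)) next
        ref <- if (k == "wt5") e else aseq
        rname[idx] <- if (k == "wt5") chrom5 else chrom3
        pos[idx] <- (if (k == "wt5") start5 else start3) + reads$a[idx] - 1L
        seqChr[idx] <- substring(ref, reads$a[idx], reads$b[idx])
        cigar[idx] <- paste0(width[idx], "M")
        revFlag[idx] <- reads$isR2[idx]
        anchorGene[idx] <- if (k == "wt5") "five_prime" else "three_prime"
    }

    fi <- which(kind == "fusion")
    if (length(fi)) {
        a <- reads$a[fi]; b <- reads$b[fi]
        tseq <- substring(template$seq, a, b)
        len5 <- pmax(0L, pmin(b, j) - a + 1L)
        len3 <- width[fi] - len5
        whole5 <- b <= j
        whole3 <- a > j
        spans <- !whole5 & !whole3
        anchor5 <- ifelse(whole5, TRUE,
            ifelse(whole3, FALSE, .anchorFive(len5, len3, config@minAnchor)))
        anchorGene[fi] <- ifelse(anchor5, "five_prime", "three_prime")
        junction[fi] <- spans
        rname[fi] <- ifelse(anchor5, chrom5, chrom3)
        revFlag[fi] <- ifelse(anchor5, reads$isR2[fi], !reads$isR2[fi])
        seqChr[fi] <- ifelse(anchor5, tseq, .revcompChr(tseq))
        ## anchored 3': the aligned part covers ref [bp3 - (b - j) + 1, ...]
        pos[fi] <- as.integer(ifelse(anchor5, start5 + a - 1L,
            bp3 - (b - j) + 1L))
        cigar[fi] <- ifelse(spans,
            ifelse(anchor5, paste0(len5, "M", len3, "S"),
                paste0(len3, "M", len5, "S")),
            paste0(width[fi], "M"))
    }

    flag <- 1L +  # paired
        ifelse(kind != "fusion", 2L, 0L) +  # proper pair (wild-type only)
        ifelse(revFlag, 16L, 0L) +
        ifelse(reads$isR2, 128L, 64L)
    ## cross-reference mates: reads are ordered (all read1, all read2)
    nr <- length(kind) %/% 2L
    mateIdx <- c(seq_len(nr) + nr, seq_len(nr))
    flag <- flag + ifelse(revFlag[mateIdx], 32L, 0L)
    rnext <- ifelse(rname[mateIdx] == rname, "=", rname[mateIdx])
    pnext <- pos[mateIdx]
    mlen <- as.integer(sub("M.*", "", cigar))  # all-M or M+S: ref width == M
    endPos <- pos + mlen - 1L
    sameChrom <- rname[mateIdx] == rname
    lo <- pmin(pos, pos[mateIdx])
    hi <- pmax(endPos, endPos[mateIdx])
    tlen <- ifelse(!sameChrom, 0L,
        ifelse(pos < pos[mateIdx] | (pos == pos[mateIdx] & !reads$isR2),
            hi - lo + 1L, -(hi - lo + 1L)))

    seqChr <- .injectErrors(seqChr, config@errorRate)
    data.frame(qname = qname[reads$frag], flag = as.integer(flag),
        rname = rname, pos = pos, mapq = 60L, cigar = cigar,
        rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
        seq = seqChr, qual = strrep("I", width),
        junction = junction, anchorGene = anchorGene,
        stringsAsFactors = FALSE)
}

.injectErrors <- function(seqs, rate) {
    if (rate <= 0)
        return(seqs)
    bases <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        n <- nchar(s)
        hit <- which(stats::runif(n) < rate)
        if (!length(hit))
            return(s)
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        for (i in hit)
            ch[i] <- sample(setdiff(bases, ch[i]), 1L)
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

.writeSam <- function(records, config, samPath) {
    chroms <- unique(c(
        as.character(GenomicRanges::seqnames(config@fivePrimeWindow)),
        as.character(GenomicRanges::seqnames(config@threePrimeWindow))))
    ln <- vapply(chroms, function(ch) {
        ends <- c(
            if (as.character(GenomicRanges::seqnames(
                config@fivePrimeWindow)) == ch)
                GenomicRanges::end(config@fivePrimeWindow),
            if (as.character(GenomicRanges::seqnames(
                config@threePrimeWindow)) == ch)
                GenomicRanges::end(config@threePrimeWindow))
        max(ends) + 1000L
    }, numeric(1))
    header <- c("@HD\tVN:1.6\tSO:unsorted",
        sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(ln)),
        "@PG\tID:ClipFusion\tPN:ClipFusion")
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
        records$qname, records$flag, records$rname, records$pos,
        records$mapq, records$cigar, records$rnext, records$pnext,
        records$tlen, records$seq, records$qual)
    writeLines(c(header, body), samPath)
    samPath
}

#' Simulate one synthetic cfDNA capture-sequencing sample
#'
#' Generates synthetic window references, draws cfDNA fragments (fusion
#' derived and wild type), oracle-aligns every read, and writes a
#' coordinate-sorted indexed BAM, the reference FASTA, and a ground-truth
#' JSON beside it. Fully deterministic given the config seed.
#'
#' The truth JSON records `fusion_present`, the breakpoints,
#' `junction_read_ids` (all reads emitted with a junction soft clip, as
#' `qname/1` or `qname/2`), `eml4_junction_read_ids` (the subset anchored
#' in the 5' window whose mate maps inside the 3' window: the records the
#' detection procedure is defined over), `pair_ids` (fragments with one
#' read per gene window) and the synthetic window reference sequences.
#'
#' @param config A [SimConfig].
#' @param outPrefix Output path prefix; writes `<prefix>.bam`,
#'   `<prefix>.bam.bai`, `<prefix>.fa` and `<prefix>_truth.json`.
#' @return Invisibly, a list with `bam`, `bai`, `fasta`, `truthJson` paths
#'   and the `truth` list itself.
#' @export
simulateSample <- function(config, outPrefix) {
    stopifnot(is(config, "SimConfig"))
    dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
    refs <- synthReferences(config)  # seeds the per-sample RNG stream
    template <- if (config@fusionFragments > 0L)
        makeFusionTemplate(config, refs) else NULL
    fragments <- sampleFragments(config)
    records <- oracleAlign(fragments, template, config, refs)

    fasta <- paste0(outPrefix, ".fa")
    faRefs <- refs
    names(faRefs) <- sprintf("%s_window_synthetic %s:%d-%d",
        names(refs),
        c(as.character(GenomicRanges::seqnames(config@fivePrimeWindow)),
          as.character(GenomicRanges::seqnames(config@threePrimeWindow))),
        c(GenomicRanges::start(config@fivePrimeWindow),
          GenomicRanges::start(config@threePrimeWindow)),
        c(GenomicRanges::end(config@fivePrimeWindow),
          GenomicRanges::end(config@threePrimeWindow)))
    Biostrings::writeXStringSet(faRefs, fasta)

    sam <- paste0(outPrefix, ".sam")
    .writeSam(records, config, sam)
    tmpBam <- Rsamtools::asBam(sam, paste0(outPrefix, ".unsorted"),
        indexDestination = FALSE, overwrite = TRUE)
    bam <- Rsamtools::sortBam(tmpBam, outPrefix)
    bai <- Rsamtools::indexBam(bam)
    unlink(c(sam, tmpBam))

    readId <- paste0(records$qname, ifelse(bitwAnd(records$flag, 128L) > 0L,
        "/2", "/1"))
    w5 <- config@fivePrimeWindow
    w3 <- config@threePrimeWindow
    chrom3 <- as.character(GenomicRanges::seqnames(w3))
    mateChrom <- ifelse(records$rnext == "=", records$rname, records$rnext)
    mateIn3 <- mateChrom == chrom3 &
        records$pnext >= GenomicRanges::start(w3) &
        records$pnext <= GenomicRanges::end(w3)
    eml4Junction <- records$junction &
        records$anchorGene == "five_prime" & mateIn3
    ## oracleAlign emits all first mates then all second mates, aligned
    nr <- nrow(records) %/% 2L
    pairIds <- records$qname[seq_len(nr)][
        records$anchorGene[seq_len(nr)] !=
            records$anchorGene[seq_len(nr) + nr]]

    truth <- list(
        fusion_present = config@fusionFragments > 0L,
        breakpoint_5p = config@breakpoint5p,
        breakpoint_3p = config@breakpoint3p,
        junction_read_ids = as.list(readId[records$junction]),
        eml4_junction_read_ids = as.list(readId[eml4Junction]),
        pair_ids = as.list(sort(pairIds)),
        n_records = nrow(records),
        seed = config@seed,
        params = list(frag_len_mean = config@fragLenMean,
            frag_len_sd = config@fragLenSd, read_len = config@readLen,
            error_rate = config@errorRate, min_anchor = config@minAnchor,
            fusion_fragments = config@fusionFragments,
            wildtype_depth = config@wildtypeDepth),
        references = list(
            five_prime = c(.regionToList(w5),
                list(seq = as.character(refs[[1L]]))),
            three_prime = c(.regionToList(w3),
                list(seq = as.character(refs[[2L]])))))
    truthJson <- paste0(outPrefix, "_truth.json")
    jsonlite::write_json(truth, truthJson, auto_unbox = TRUE, pretty = TRUE)
    invisible(list(bam = bam, bai = bai, fasta = fasta,
        truthJson = truthJson, truth = truth))
}
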