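## Shared fixtures: small synthetic gene windows, hand-crafted BAM
## construction, and independent brute-force oracles.

testWindows <- function(size = 5000L, w5start = 1000000L,
                        w3start = 2000000L) {
    list(
        w5 = geneRegion("chr2", w5start, w5start + size - 1L,
            label = "EML4", strand = "+"),
        w3 = geneRegion("chr2", w3start, w3start + size - 1L,
            label = "ALK", strand = "-"))
}

testSimConfig <- function(seed, fusionFragments = 80L, wildtypeDepth = 30,
                          size = 5000L, ...) {
    w <- testWindows(size)
    SimConfig(seed = seed, fivePrimeWindow = w$w5, threePrimeWindow = w$w3,
        fusionFragments = fusionFragments, wildtypeDepth = wildtypeDepth,
        ...)
}

testTarget <- function(size = 5000L, ...) {
    w <- testWindows(size)
    FusionTarget("EML4-ALK-test", "synthetic", fivePrime = w$w5,
        threePrime = w$w3, ...)
}

## In-memory alignment records for unit-testing the detection operations
## without touching a BAM.
makeGA <- function(pos, cigar, qname = sprintf("q%02d", seq_along(pos)),
                   mpos = 2000500L, mrnm = "chr2", seq = NULL,
                   chrom = "chr2", flag = 65L) {
    n <- length(pos)
    qwidth <- vapply(cigar, function(cg) {
        lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
        ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
        sum(lens[ops %in% c("M", "I", "S", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
    if (is.null(seq))
        seq <- strrep("A", qwidth)
    ga <- GenomicAlignments::GAlignments(
        seqnames = S4Vectors::Rle(chrom, n),
        pos = as.integer(pos), cigar = cigar,
        strand = S4Vectors::Rle(GenomicRanges::strand("+"), n))
    S4Vectors::mcols(ga)$qname <- rep_len(qname, n)
    S4Vectors::mcols(ga)$flag <- rep_len(as.integer(flag), n)
    S4Vectors::mcols(ga)$seq <- Biostrings::DNAStringSet(seq)
    S4Vectors::mcols(ga)$mrnm <- rep_len(mrnm, n)
    S4Vectors::mcols(ga)$mpos <- rep_len(as.integer(mpos), n)
    S4Vectors::mcols(ga)$mapq <- rep_len(60L, n)
    ga
}

## One SAM record as a tab-separated line; seq defaults to a run of A
## matching the query-consuming CIGAR length.
samLine <- function(qname, flag, pos, cigar, rname = "chr2",
                    mapq = 60L, rnext = "=", pnext = 1L, tlen = 0L,
                    seq = NULL) {
    if (is.null(seq)) {
        lens <- as.integer(regmatches(cigar,
            gregexpr("[0-9]+", cigar))[[1L]])
        ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
        seq <- strrep("A", sum(lens[ops %in% c("M", "I", "S", "=", "X")]))
    }
    paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

## Write a sorted, indexed BAM from SAM record lines.
writeTestBam <- function(lines, dir = tempfile("bamdir"),
                         chroms = c(chr2 = 3000000L), index = TRUE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sam <- file.path(dir, "test.sam")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
        sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms), lines), sam)
    tmp <- Rsamtools::asBam(sam, file.path(dir, "unsorted"),
        indexDestination = FALSE, overwrite = TRUE)
    bam <- Rsamtools::sortBam(tmp, file.path(dir, "test"))
    if (index) Rsamtools::indexBam(bam)
    bam
}

## Independent Fisher oracle: enumerate every integer table with the
## observed margins and sum the probabilities (binomial-coefficient form)
## of those no more probable than the observed table.
bruteFisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    xs <- max(0, k - n):min(k, m)
    pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
    pObs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
    min(1, sum(pr[pr <= pObs * (1 + 1e-7)]))
}

## Independent region scan: read the whole BAM without an index or flag
## filter, recompute each record's reference span from the CIGAR text,
## and filter by overlap and flag bits manually.
naiveRegionScan <- function(bam, region) {
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
        "cigar"))
    x <- Rsamtools::scanBam(bam, param = p)[[1L]]
    refWidth <- vapply(x$cigar, function(cg) {
        lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
        ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
        sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
    bad <- 4L + 8L + 256L + 512L + 1024L + 2048L
    keep <- bitwAnd(x$flag, bad) == 0L &
        as.character(x$rname) == as.character(GenomicRanges::seqnames(region)) &
        x$pos <= GenomicRanges::end(region) &
        x$pos + refWidth - 1L >= GenomicRanges::start(region)
    sort(paste(x$qname[keep], x$flag[keep], x$pos[keep], sep = "|"))
}

## Key set of a streamed GAlignments for comparison with naiveRegionScan.
streamKeys <- function(reads) {
    m <- S4Vectors::mcols(reads)
    sort(paste(m$qname, m$flag, GenomicRanges::start(reads), sep = "|"))
}

## Independent breakpoint-depth oracle: parse `samtools view` text and
## walk the CIGAR counting reads whose M/D/=/X span covers the position.
samtoolsDepthOracle <- function(bam, chrom, pos) {
    out <- system2("samtools", c("view", bam,
        sprintf("%s:%d-%d", chrom, pos, pos)), stdout = TRUE)
    if (length(out) == 0L) return(0L)
    fields <- strsplit(out, "\t", fixed = TRUE)
    flag <- as.integer(vapply(fields, `[[`, "", 2L))
    start <- as.integer(vapply(fields, `[[`, "", 4L))
    cig <- vapply(fields, `[[`, "", 6L)
    bad <- 4L + 8L + 256L + 512L + 1024L + 2048L
    covers <- mapply(function(p, cg) {
        lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
        ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
        cur <- p
        hit <- FALSE
        for (i in seq_along(ops)) {
            if (ops[i] %in% c("M", "D", "=", "X")) {
                if (pos >= cur && pos <= cur + lens[i] - 1L) hit <- TRUE
                cur <- cur + lens[i]
            } else if (ops[i] == "N") cur <- cur + lens[i]
        }
        hit
    }, start, cig)
    sum(covers & bitwAnd(flag, bad) == 0L)
}

## Reverse complement for truth-side arithmetic, independent of the
## package's helper.
rcChr <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1L]]]), collapse = "")
}
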