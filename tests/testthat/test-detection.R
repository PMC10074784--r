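target <- testTarget()  # EML4 chr2:1,000,000-1,004,999; ALK chr2:2,000,000-2,004,999

test_that("mate filtering keeps exactly the reads whose mate lies in the 3' window", {
    w3 <- threePrimeRegion(target)
    s3 <- GenomicRanges::start(w3)
    e3 <- GenomicRanges::end(w3)
    ga <- makeGA(pos = rep(1000100L, 6), cigar = rep("100M", 6),
        qname = paste0("q", 1:6),
        mpos = c(s3, e3, s3 - 1L, e3 + 1L, s3 + 1000L, s3 + 1000L),
        mrnm = c(rep("chr2", 5), "chr1"))
    kept <- selectMatePairs(ga, target)
    expect_equal(S4Vectors::mcols(kept)$qname, c("q1", "q2", "q5"))
    ## mate-chromosome dialect is reconciled
    ga2 <- makeGA(pos = 1000100L, cigar = "100M", mpos = s3 + 10L,
        mrnm = "2")
    expect_length(selectMatePairs(ga2, target), 1L)
    ## empty in, empty out
    expect_length(selectMatePairs(ga[0], target), 0L)
})

test_that("soft-clip evidence carries the documented clip end, length and breakpoint", {
    p <- 1000200L
    ga <- makeGA(pos = rep(p, 4),
        cigar = c("58M42S", "100M", "42S58M", "5S60M35S"),
        qname = paste0("q", 1:4))
    ev <- identifySoftclips(ga, target)
    m <- S4Vectors::mcols(ev)
    expect_equal(m$qname, c("q1", "q3", "q4"))  # 100M contributes nothing
    ## right-end clip: breakpoint = pos + reference width - 1
    expect_equal(m$clipEnd[1], "right")
    expect_equal(m$clipLen[1], 42L)
    expect_equal(m$breakpoint[1], p + 58L - 1L)
    ## left-end clip: breakpoint = pos
    expect_equal(m$clipEnd[2], "left")
    expect_equal(m$breakpoint[2], p)
    ## both ends clipped: the longer clip wins
    expect_equal(m$clipEnd[3], "right")
    expect_equal(m$clipLen[3], 35L)
    expect_equal(m$breakpoint[3], p + 60L - 1L)
})

test_that("clipped subsequences are taken from the correct read end", {
    seq <- paste0(strrep("C", 58), strrep("G", 42))
    ga <- makeGA(pos = 1000200L, cigar = "58M42S", seq = seq)
    ev <- identifySoftclips(ga, target)
    expect_equal(S4Vectors::mcols(ev)$clippedSeq, strrep("G", 42))
    seqL <- paste0(strrep("G", 42), strrep("C", 58))
    gaL <- makeGA(pos = 1000200L, cigar = "42S58M", seq = seqL)
    evL <- identifySoftclips(gaL, target)
    expect_equal(S4Vectors::mcols(evL)$clippedSeq, strrep("G", 42))
})

test_that("breakpoint inference takes the mode, ties toward the smallest position", {
    p <- 1000300L
    ga <- makeGA(pos = c(p, p, p + 1L), cigar = rep("50M50S", 3))
    bp <- inferBreakpoint(identifySoftclips(ga, target))
    expect_equal(bp$consensus, p + 49L)
    expect_equal(unname(bp$table), c(2L, 1L))
    expect_equal(names(bp$table), as.character(c(p + 49L, p + 50L)))
    ## single read
    one <- identifySoftclips(makeGA(p, "50M50S"), target)
    expect_equal(inferBreakpoint(one)$consensus, p + 49L)
    ## 2 vs 2 tie -> smallest coordinate
    tie <- identifySoftclips(makeGA(c(p, p, p + 3L, p + 3L),
        cigar = rep("50M50S", 4)), target)
    expect_equal(inferBreakpoint(tie)$consensus, p + 49L)
    expect_error(inferBreakpoint(one[0]), "junction")
})

test_that("5' flank consensus resolves ties to N and honours flank length", {
    p <- 1000103L  # breakpoint of 4M2S at pos 1000100
    ga <- makeGA(pos = c(1000100L, 1000100L), cigar = c("4M2S", "4M2S"),
        seq = c("ACGTNN", "ACGANN"))
    ev <- identifySoftclips(ga, target)
    expect_equal(fivePrimeFlank(ev, p, 4L), "ACGN")  # last column ties
    expect_equal(fivePrimeFlank(ev, p, 2L), "GN")
    expect_equal(fivePrimeFlank(ev, p, 0L), "")
    ## columns left of all coverage emit N
    expect_equal(fivePrimeFlank(ev, p, 6L), "NNACGN")
})

test_that("3' flank consensus uses clipped bases walking away from the junction", {
    p <- 1000149L
    ga <- makeGA(pos = 1000100L, cigar = "50M6S",
        seq = paste0(strrep("A", 50), "TGCACT"))
    ev <- identifySoftclips(ga, target)
    ## single evidence read: its clipped bases verbatim
    expect_equal(threePrimeFlank(ev, p, 20L), "TGCACT")
    expect_equal(threePrimeFlank(ev, p, 3L), "TGC")
    ## clips shorter than flankLen: output length = longest clip
    ga2 <- makeGA(pos = c(1000100L, 1000100L), cigar = c("50M6S", "50M4S"),
        seq = c(paste0(strrep("A", 50), "TGCACT"),
                paste0(strrep("A", 50), "TGCA")))
    ev2 <- identifySoftclips(ga2, target)
    expect_equal(threePrimeFlank(ev2, p, 20L), "TGCACT")
    ## a left-clip read votes with its junction-adjacent bases first
    gaL <- makeGA(pos = 1000150L, cigar = "6S50M",
        seq = paste0("TCACGT", strrep("A", 50)))
    evL <- identifySoftclips(gaL, target)
    expect_equal(threePrimeFlank(evL, 1000150L, 6L), "TGCACT")
})

test_that("breakpoint depth counts M/D/=/X spans but not N skips", {
    q <- 1000500L
    lines <- c(
        samLine("covM", 65L, q - 10L, "100M"),
        samLine("covD", 65L, q - 55L, "50M10D50M"),   # D segment spans q
        samLine("skipN", 65L, q - 55L, "50M10N50M"),  # N segment spans q
        samLine("away", 65L, q + 500L, "100M"))
    bam <- writeTestBam(lines)
    expect_equal(breakpointDepth(bam, target, q), 2L)
    expect_equal(breakpointDepth(bam, target, 1000L), 0L)
    expect_error(breakpointDepth(bam, target, NA), "consensus")
})

test_that("detection composes: thresholds, negativity contract, empty input", {
    ## empty five-prime window: negative, empty evidence, no error
    bam0 <- writeTestBam(samLine("far", 65L, 2500000L, "100M"))
    call0 <- detectFusion(bam0, target)
    expect_equal(fusionStatus(call0), "negative")
    expect_length(evidenceReads(call0), 0L)
    expect_true(is.na(consensusBreakpoint(call0)))
    expect_true(all(is.na(flankSequences(call0))))

    ## 3 mate pairs but exactly 1 soft-clipped read: negative at defaults,
    ## positive when min_clip_reads = 1
    lines <- c(
        samLine("p1", 65L, 1000100L, "100M", pnext = 2000100L),
        samLine("p2", 65L, 1000150L, "100M", pnext = 2000150L),
        samLine("p3", 65L, 1000200L, "58M42S", pnext = 2000200L))
    bam <- writeTestBam(lines)
    call <- detectFusion(bam, target)
    expect_equal(fusionStatus(call), "negative")
    expect_equal(nPairs(call), 3L)
    expect_equal(nClipReads(call), 1L)
    relaxed <- testTarget(minClipReads = 1L)
    expect_equal(fusionStatus(detectFusion(bam, relaxed)), "positive")
})

test_that("threshold monotonicity: support only helps, thresholds only hinder", {
    lines <- c(
        samLine("p1", 65L, 1000100L, "60M40S", pnext = 2000100L),
        samLine("p2", 65L, 1000110L, "50M50S", pnext = 2000150L))
    moreLines <- c(lines,
        samLine("p3", 65L, 1000120L, "40M60S", pnext = 2000200L))
    bam <- writeTestBam(lines)
    bamMore <- writeTestBam(moreLines)
    expect_equal(fusionStatus(detectFusion(bam, target)), "positive")
    ## adding junction-supporting records never flips positive -> negative
    expect_equal(fusionStatus(detectFusion(bamMore, target)), "positive")
    ## raising either threshold never flips negative -> positive
    statuses <- vapply(1:4, function(th) fusionStatus(detectFusion(bam,
        testTarget(minPairs = th, minClipReads = th))), character(1))
    expect_false(is.unsorted(rev(as.integer(statuses == "positive"))))
    strict <- testTarget(minPairs = 3L, minClipReads = 3L)
    expect_equal(fusionStatus(detectFusion(bam, strict)), "negative")
    expect_equal(fusionStatus(detectFusion(bamMore, strict)), "positive")
})

test_that("evidence reads are sound and counts match a whole-file rescan", {
    cfg <- testSimConfig(seed = 21L, fusionFragments = 70L,
        wildtypeDepth = 20)
    sim <- simulateSample(cfg, file.path(tempfile("sim"), "s"))
    tgt <- simTarget(cfg)
    call <- detectFusion(sim$bam, tgt)
    expect_equal(fusionStatus(call), "positive")
    ev <- evidenceReads(call)
    w5 <- fivePrimeRegion(tgt); w3 <- threePrimeRegion(tgt)
    m <- S4Vectors::mcols(ev)
    expect_true(all(GenomicRanges::start(ev) <= GenomicRanges::end(w5) &
        GenomicRanges::end(ev) >= GenomicRanges::start(w5)))
    expect_true(all(m$mpos >= GenomicRanges::start(w3) &
        m$mpos <= GenomicRanges::end(w3)))
    expect_true(all(hasSoftclip(GenomicAlignments::cigar(ev))))

    ## naive whole-file rescan oracle for nPairs / nClipReads
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
        "cigar", "mrnm", "mpos"))
    x <- Rsamtools::scanBam(sim$bam, param = p)[[1L]]
    refWidth <- vapply(x$cigar, function(cg) {
        lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1L]])
        ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1L]]
        sum(lens[ops %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
    bad <- 4L + 8L + 256L + 512L + 1024L + 2048L
    inWin <- bitwAnd(x$flag, bad) == 0L &
        as.character(x$rname) == "chr2" &
        x$pos <= GenomicRanges::end(w5) &
        x$pos + refWidth - 1L >= GenomicRanges::start(w5)
    mateIn <- as.character(x$mrnm) == "chr2" &
        x$mpos >= GenomicRanges::start(w3) &
        x$mpos <= GenomicRanges::end(w3)
    cand <- inWin & mateIn
    expect_equal(nPairs(call), length(unique(x$qname[cand])))
    clipped <- cand & grepl("S", x$cigar, fixed = TRUE)
    expect_equal(nClipReads(call), sum(clipped))
})

test_that("identical input yields a bitwise-stable report", {
    cfg <- testSimConfig(seed = 33L, fusionFragments = 60L,
        wildtypeDepth = 15)
    sim <- simulateSample(cfg, file.path(tempfile("sim"), "s"))
    tgt <- simTarget(cfg)
    f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
    writeFusionReport(detectFusion(sim$bam, tgt), f1)
    writeFusionReport(detectFusion(sim$bam, tgt), f2)
    expect_identical(readLines(f1), readLines(f2))
})
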