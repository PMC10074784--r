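## Built-in fusion target windows. hg38 values are the EML4/ALK RefSeq gene
## spans; hg19 values are the corresponding gene spans on hg19 (derived, see
## inst/extdata/eml4_alk_hg19.json).
.BUILTIN_TARGETS <- list(
    "EML4-ALK" = list(
        hg38 = list(
            five_prime = list(chrom = "chr2", start = 42169353L,
                end = 42332548L, strand = "+", label = "EML4"),
            three_prime = list(chrom = "chr2", start = 29192774L,
                end = 29921586L, strand = "-", label = "ALK")
        ),
        hg19 = list(
            five_prime = list(chrom = "chr2", start = 42396490L,
                end = 42559688L, strand = "+", label = "EML4"),
            three_prime = list(chrom = "chr2", start = 29415640L,
                end = 30144432L, strand = "-", label = "ALK")
        )
    )
)

#' Construct a single-gene genomic window
#'
#' Helper building the length-1 `GRanges` used for the 5' and 3' partner
#' windows of a [FusionTarget]. Coordinates are 1-based inclusive; strand is
#' annotation only.
#'
#' @param chrom Chromosome name (non-empty).
#' @param start,end 1-based inclusive window bounds, `start <= end`,
#'   `start >= 1`.
#' @param label Gene symbol carried in `mcols()$label`.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A `GRanges` of length 1.
#' @examples
#' geneRegion("chr2", 42169353, 42332548, label = "EML4")
#' @export
geneRegion <- function(chrom, start, end, label, strand = "*") {
    if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom) ||
        !nzchar(chrom))
        stop("gene region: 'chrom' must be a non-empty string")
    start <- .asCount(start, "start")
    end <- .asCount(end, "end")
    if (start < 1L)
        stop("gene region '", label, "': start must be >= 1")
    if (start > end)
        stop("gene region '", label, "': start (", start,
            ") must be <= end (", end, ")")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
        strand = strand)
    gr$label <- as.character(label)
    gr
}

.asCount <- function(x, what) {
    if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x))
        stop("'", what, "' must be a single integer, got: ",
            paste(format(x), collapse = ","))
    as.integer(x)
}

#' Construct a fusion target configuration
#'
#' @param name Target identifier, e.g. `"EML4-ALK"`.
#' @param build Genome build tag (`"hg38"` or `"hg19"` for the built-in
#'   target; free-form for custom targets).
#' @param fivePrime,threePrime Length-1 `GRanges` as returned by
#'   [geneRegion()]: the window scanned for reads and the window the mate
#'   must fall in.
#' @param minPairs,minClipReads Detection thresholds; both default to 2.
#' @param flankLen Reported flank length per breakpoint side; default 20.
#' @return A validated [FusionTarget].
#' @seealso [builtinTarget()], [loadTargetConfig()]
#' @export
FusionTarget <- function(name, build, fivePrime, threePrime,
                         minPairs = 2L, minClipReads = 2L, flankLen = 20L) {
    new("FusionTarget",
        name = as.character(name), build = as.character(build),
        fivePrime = fivePrime, threePrime = threePrime,
        minPairs = .asCount(minPairs, "min_pairs"),
        minClipReads = .asCount(minClipReads, "min_clip_reads"),
        flankLen = .asCount(flankLen, "flank_len"))
}

#' Built-in fusion targets
#'
#' Returns the shipped configuration for a known fusion target. For
#' `"EML4-ALK"` on hg38 these are the windows EML4 chr2:42,169,353-42,332,548
#' and ALK chr2:29,192,774-29,921,586 with default thresholds
#' `minPairs = 2`, `minClipReads = 2`. The hg19 windows are the corresponding
#' gene spans on that build (shipped as derived data; override with
#' [loadTargetConfig()] if needed).
#'
#' @param name Built-in target name; currently `"EML4-ALK"`.
#' @param build `"hg38"` or `"hg19"`.
#' @return A validated [FusionTarget].
#' @examples
#' builtinTarget("EML4-ALK", "hg38")
#' @export
builtinTarget <- function(name = "EML4-ALK", build = c("hg38", "hg19")) {
    if (!name %in% names(.BUILTIN_TARGETS))
        stop("unknown fusion target '", name, "'; supported targets: ",
            paste(names(.BUILTIN_TARGETS), collapse = ", "))
    builds <- names(.BUILTIN_TARGETS[[name]])
    if (length(build) > 1L) build <- build[[1L]]
    if (!build %in% builds)
        stop("unknown genome build '", build, "' for target '", name,
            "'; supported builds: ", paste(builds, collapse = ", "))
    b <- .BUILTIN_TARGETS[[name]][[build]]
    FusionTarget(name, build,
        fivePrime = do.call(geneRegion, b$five_prime),
        threePrime = do.call(geneRegion, b$three_prime))
}

.regionFromList <- function(x, what) {
    need <- c("chrom", "start", "end", "label")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("target config: region '", what, "' is missing field(s): ",
            paste(miss, collapse = ", "))
    geneRegion(x$chrom, x$start, x$end, label = x$label,
        strand = if (is.null(x$strand)) "*" else x$strand)
}

#' Load a fusion target configuration from JSON
#'
#' The document must carry the keys `name`, `build`, `five_prime`,
#' `three_prime` (each region an object with `chrom`, `start`, `end`,
#' `label` and optional `strand`), and optionally `min_pairs`,
#' `min_clip_reads` and `flank_len` (defaults 2 / 2 / 20). All invariants
#' are enforced; violations name the offending field.
#'
#' @param path Path to a JSON target configuration.
#' @return A validated [FusionTarget].
#' @examples
#' cfg <- system.file("extdata", "eml4_alk_hg38.json", package = "ClipFusion")
#' loadTargetConfig(cfg)
#' @export
loadTargetConfig <- function(path) {
    if (!file.exists(path))
        stop("target config file not found: ", path)
    x <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
        error = function(e)
            stop("target config '", path, "' is not valid JSON: ",
                conditionMessage(e), call. = FALSE))
    need <- c("name", "build", "five_prime", "three_prime")
    miss <- setdiff(need, names(x))
    if (length(miss))
        stop("target config: missing field(s): ",
            paste(miss, collapse = ", "))
    FusionTarget(x$name, x$build,
        fivePrime = .regionFromList(x$five_prime, "five_prime"),
        threePrime = .regionFromList(x$three_prime, "three_prime"),
        minPairs = if (is.null(x$min_pairs)) 2L else x$min_pairs,
        minClipReads = if (is.null(x$min_clip_reads)) 2L else
            x$min_clip_reads,
        flankLen = if (is.null(x$flank_len)) 20L else x$flank_len)
}

.regionToList <- function(gr) {
    list(chrom = as.character(GenomicRanges::seqnames(gr)),
        start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
        strand = as.character(GenomicRanges::strand(gr)), label = gr$label)
}

#' Write a fusion target configuration to JSON
#'
#' Inverse of [loadTargetConfig()]: `loadTargetConfig(writeTargetConfig(x, p))`
#' reproduces `x`.
#'
#' @param target A [FusionTarget].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTargetConfig <- function(target, path) {
    stopifnot(is(target, "FusionTarget"))
    x <- list(name = target@name, build = target@build,
        five_prime = .regionToList(target@fivePrime),
        three_prime = .regionToList(target@threePrime),
        min_pairs = target@minPairs, min_clip_reads = target@minClipReads,
        flank_len = target@flankLen)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' @describeIn FusionTarget-class The 5' partner (scanned) gene window.
#' @param x A `FusionTarget`.
#' @export
fivePrimeRegion <- function(x) x@fivePrime

#' @describeIn FusionTarget-class The 3' partner (mate) gene window.
#' @export
threePrimeRegion <- function(x) x@threePrime

#' @describeIn FusionTarget-class Minimum mate-pair count for positivity.
#' @export
minPairs <- function(x) x@minPairs

#' @describeIn FusionTarget-class Minimum clipped-read count for positivity.
#' @export
minClipReads <- function(x) x@minClipReads

#' @describeIn FusionTarget-class Reported flank length (bp) per side.
#' @export
flankLen <- function(x) x@flankLen

.fmtRegion <- function(gr) {
    sprintf("%s %s:%s-%s (%s)", gr$label,
        as.character(GenomicRanges::seqnames(gr)),
        format(GenomicRanges::start(gr), big.mark = ","),
        format(GenomicRanges::end(gr), big.mark = ","),
        as.character(GenomicRanges::strand(gr)))
}

setMethod("show", "FusionTarget", function(object) {
    cat("FusionTarget:", object@name, sprintf("[%s]\n", object@build))
    cat("  5' partner:", .fmtRegion(object@fivePrime), "\n")
    cat("  3' partner:", .fmtRegion(object@threePrime), "\n")
    cat(sprintf("  thresholds: min_pairs=%d, min_clip_reads=%d, flank_len=%d\n",
        object@minPairs, object@minClipReads, object@flankLen))
})
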