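#' @importFrom GenomicAlignments readGAlignments cigar qwidth
#'   explodeCigarOps explodeCigarOpLengths cigarRangesAlongReferenceSpace
#'   sequenceLayer GAlignments
#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBamHeader
#'   scanBam asBam sortBam indexBam
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#'   writeXStringSet
NULL

.CIGAR_OPS <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")

#' Parse a SAM CIGAR string
#'
#' Losslessly decomposes a CIGAR string into its run-length operations.
#' Malformed text (empty string, unknown operation letter, missing or
#' trailing digits) is a parse failure.
#'
#' @param cigar A single CIGAR string, e.g. `"58M42S"`.
#' @return A `data.frame` with columns `length` (integer) and `op`
#'   (character, one of M, I, D, N, S, H, P, =, X), one row per operation in
#'   order.
#' @examples
#' parseCigar("58M42S")
#' hasSoftclip("58M42S")
#' @seealso [formatCigar()], [hasSoftclip()]
#' @export
parseCigar <- function(cigar) {
    if (!is.character(cigar) || length(cigar) != 1L || is.na(cigar))
        stop("'cigar' must be a single string")
    if (!grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
        stop("malformed CIGAR string: '", cigar, "'")
    out <- data.frame(
        length = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]],
        op = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
        stringsAsFactors = FALSE)
    if (any(out$length < 1L))
        stop("malformed CIGAR string (zero-length operation): '", cigar, "'")
    out
}

#' Format a parsed CIGAR back to text
#'
#' Inverse of [parseCigar()]: `formatCigar(parseCigar(x)) == x` for every
#' valid CIGAR `x`.
#'
#' @param ops A `data.frame` with columns `length` and `op`.
#' @return A CIGAR string.
#' @export
formatCigar <- function(ops) {
    stopifnot(is.data.frame(ops), all(c("length", "op") %in% names(ops)))
    if (nrow(ops) == 0L || any(ops$length < 1L) ||
        !all(ops$op %in% .CIGAR_OPS))
        stop("invalid CIGAR operation list")
    paste0(ops$length, ops$op, collapse = "")
}

#' Does a CIGAR contain a soft clip?
#'
#' Vectorized test for an `"S"` operation; junction-spanning reads carry the
#' partner gene's bases as a soft clip.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Logical vector.
#' @export
hasSoftclip <- function(cigar) {
    grepl("S", cigar, fixed = TRUE)
}

## Default record filter: drop unmapped, mate-unmapped, secondary,
## supplementary, QC-fail and duplicate-flagged records. Inputs are modeled
## as position-deduplicated; duplicates and split-alignment artifacts must
## not inflate evidence counts.
.defaultFlagFilter <- function() {
    Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE,
        hasUnmappedMate = FALSE,
        isSecondaryAlignment = FALSE,
        isSupplementaryAlignment = FALSE,
        isNotPassingQualityControls = FALSE,
        isDuplicate = FALSE)
}

.bamIndexPath <- function(bam) {
    cands <- c(paste0(bam, ".bai"),
        paste0(tools::file_path_sans_ext(bam), ".bai"))
    hit <- cands[file.exists(cands)]
    if (length(hit)) hit[[1L]] else NA_character_
}

.checkIndexedBam <- function(bam) {
    if (!file.exists(bam))
        stop("BAM file not found: ", bam)
    idx <- .bamIndexPath(bam)
    if (is.na(idx))
        stop("no index found for '", bam,
            "'; create one with Rsamtools::indexBam() or `samtools index`")
    idx
}

## Reconcile the "chr2" vs "2" chromosome-name dialects against the BAM
## header: try the configured name, then its alternate form.
.resolveChrom <- function(bam, chrom) {
    header <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    known <- names(header)
    if (chrom %in% known)
        return(chrom)
    alt <- if (grepl("^chr", chrom)) sub("^chr", "", chrom) else
        paste0("chr", chrom)
    if (alt %in% known)
        return(alt)
    stop("chromosome '", chrom, "' (or '", alt,
        "') not present in the header of '", bam, "'")
}

#' Stream filter-passing reads overlapping a genomic window
#'
#' Reads all records whose aligned reference span (CIGAR operations
#' M/D/N/=/X) overlaps `region` and that pass the flag filter, from a
#' coordinate-sorted, indexed BAM. The default filter excludes unmapped,
#' mate-unmapped, secondary, supplementary, QC-fail and duplicate records;
#' no mapping-quality threshold is applied unless `minMapq` is set.
#' Chromosome-name dialects (`"chr2"` vs `"2"`) are reconciled against the
#' BAM header automatically.
#'
#' @param bam Path to a coordinate-sorted BAM with a BAI index.
#' @param region Length-1 `GRanges` (see [geneRegion()]).
#' @param minMapq Optional minimum mapping quality (default: no threshold).
#' @param flag A `scanBamFlag()` filter; the default is described above.
#' @return A [GenomicAlignments::GAlignments] with metadata columns `qname`,
#'   `flag`, `seq`, `mrnm` (mate chromosome), `mpos` (1-based mate position)
#'   and `mapq`.
#' @export
streamRegionReads <- function(bam, region, minMapq = NA_integer_,
                              flag = .defaultFlagFilter()) {
    .checkIndexedBam(bam)
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    chrom <- .resolveChrom(bam, as.character(GenomicRanges::seqnames(region)))
    which <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(GenomicRanges::start(region),
            GenomicRanges::end(region)))
    param <- Rsamtools::ScanBamParam(
        flag = flag,
        what = c("qname", "flag", "seq", "mrnm", "mpos", "mapq"),
        which = which,
        mapqFilter = if (is.na(minMapq)) NA_integer_ else as.integer(minMapq))
    GenomicAlignments::readGAlignments(Rsamtools::BamFile(bam), param = param)
}
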