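#' Run fusion detection across a cohort manifest
#'
#' The manifest is a TSV with one row per sample: columns `sample` and
#' `bam` (paths), optionally `truth` (`positive`/`negative` labels) and
#' any number of extra detection-status columns from other callers. Every
#' BAM is analysed with [detectFusion()]; if truth labels are present a
#' [confusionSummary()] is computed; if `compare` names two status columns
#' (either of which may be `"clipfusion"`, this package's own calls) their
#' detected/not-detected counts are laid out as a 2x2 table and compared
#' with [fisherExactTwoSided()].
#'
#' @param manifest Path to the manifest TSV, or an equivalent
#'   `data.frame`.
#' @param target A [FusionTarget].
#' @param compare Optional character vector of two status column names to
#'   compare.
#' @return A list with `calls` (per-sample summary `data.frame`),
#'   `metrics` (list with `confusion` and/or `comparison`, as available).
#' @export
runCohort <- function(manifest, target = builtinTarget("EML4-ALK", "hg38"),
                      compare = NULL) {
    if (is.character(manifest)) {
        if (!file.exists(manifest))
            stop("manifest not found: ", manifest)
        manifest <- utils::read.delim(manifest, sep = "\t",
            stringsAsFactors = FALSE, check.names = FALSE)
    }
    stopifnot(is.data.frame(manifest))
    if (nrow(manifest) == 0L)
        stop("manifest is empty")
    if (!"sample" %in% names(manifest))
        stop("manifest must have a 'sample' column")
    if (anyDuplicated(manifest$sample))
        stop("duplicated sample id(s): ", paste(unique(
            manifest$sample[duplicated(manifest$sample)]), collapse = ", "))
    calls <- NULL
    if ("bam" %in% names(manifest)) {
        bad <- manifest$sample[!file.exists(manifest$bam)]
        if (length(bad))
            stop("BAM path unreadable for sample(s): ",
                paste(bad, collapse = ", "))
        rows <- lapply(seq_len(nrow(manifest)), function(i)
            fusionSummaryRow(detectFusion(manifest$bam[i], target),
                manifest$sample[i]))
        calls <- do.call(rbind, rows)
        manifest$clipfusion <- calls$status
    }
    metrics <- list()
    if ("truth" %in% names(manifest) && !is.null(calls)) {
        metrics$confusion <- confusionSummary(
            data.frame(sample = calls$sample, status = calls$status),
            data.frame(sample = manifest$sample, status = manifest$truth))
    }
    if (!is.null(compare)) {
        if (length(compare) != 2L || !all(compare %in% names(manifest)))
            stop("'compare' must name two status columns of the manifest; ",
                "available: ", paste(names(manifest), collapse = ", "))
        det <- lapply(compare, function(cn) {
            s <- tolower(as.character(manifest[[cn]]))
            if (!all(s %in% c("positive", "negative")))
                stop("column '", cn,
                    "' must contain 'positive'/'negative' values")
            s == "positive"
        })
        tab <- c(a = sum(det[[1L]]), b = sum(!det[[1L]]),
            c = sum(det[[2L]]), d = sum(!det[[2L]]))
        metrics$comparison <- list(
            methods = compare,
            detected = c(tab[["a"]], tab[["c"]]),
            not_detected = c(tab[["b"]], tab[["d"]]),
            fisher_p = fisherExactTwoSided(tab[["a"]], tab[["b"]],
                tab[["c"]], tab[["d"]]))
    }
    list(calls = calls, metrics = metrics)
}
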