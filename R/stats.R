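#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-mass rule: with margins
#' fixed, the p-value is the sum of the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed
#' table (the comparison uses a relative tolerance of 1e-7, so tables tied
#' with the observed one up to floating-point noise are included). This is
#' the mainstream two-sided definition (the one `stats::fisher.test`
#' implements); it is stated explicitly here because two-sided Fisher
#' conventions vary between texts.
#'
#' @param a,b,c,d Non-negative integer counts, row-wise: row 1 = method 1
#'   detected / not detected, row 2 = method 2 detected / not detected.
#'   Alternatively pass a 2x2 matrix as `a`.
#' @return The two-sided p-value in `(0, 1]`.
#' @examples
#' ## 15/41 vs 25/41 samples detected by two callers
#' fisherExactTwoSided(15, 26, 25, 16)
#' @export
fisherExactTwoSided <- function(a, b = NULL, c = NULL, d = NULL) {
    if (is.matrix(a)) {
        stopifnot(identical(dim(a), c(2L, 2L)))
        d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
    }
    counts <- c(a = a, b = b, c = c, d = d)
    if (any(!is.finite(counts)) || any(counts < 0) ||
        any(counts != round(counts)))
        stop("all four counts must be non-negative integers")
    if (sum(counts) == 0)
        stop("at least one count must be positive")
    m <- a + b      # row-1 margin
    n <- c + d      # row-2 margin
    k <- a + c      # column-1 margin
    x <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(x, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Sensitivity/specificity summary of predicted versus true fusion status
#'
#' @param calls `data.frame` with columns `sample` and `status`
#'   (`"positive"`/`"negative"`, or logical) as predicted.
#' @param truth `data.frame` with the same columns holding the true
#'   status; every predicted sample id must be present here.
#' @return A list with `tp`, `fp`, `tn`, `fn`, `sensitivity`
#'   (`TP/(TP+FN)`) and `specificity` (`TN/(TN+FP)`). An undefined ratio
#'   (no true positives, or no true negatives) is reported as `NA`, never
#'   as 0.
#' @examples
#' confusionSummary(
#'     data.frame(sample = c("s1", "s2"), status = c("positive", "negative")),
#'     data.frame(sample = c("s1", "s2"), status = c("positive", "negative")))
#' @export
confusionSummary <- function(calls, truth) {
    norm <- function(x) {
        if (is.logical(x)) return(x)
        s <- tolower(as.character(x))
        if (!all(s %in% c("positive", "negative")))
            stop("status values must be 'positive'/'negative' or logical")
        s == "positive"
    }
    stopifnot(all(c("sample", "status") %in% names(calls)),
        all(c("sample", "status") %in% names(truth)))
    missing <- setdiff(calls$sample, truth$sample)
    if (length(missing))
        stop("sample id(s) missing from truth: ",
            paste(missing, collapse = ", "))
    pred <- norm(calls$status)
    tru <- norm(truth$status)[match(calls$sample, truth$sample)]
    tp <- sum(pred & tru)
    fp <- sum(pred & !tru)
    tn <- sum(!pred & !tru)
    fn <- sum(!pred & tru)
    list(tp = tp, fp = fp, tn = tn, fn = fn,
        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
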