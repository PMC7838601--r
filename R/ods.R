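#' Overlapping density score (ODS) across CNV call sets
#'
#' Concordance score for comparing the call sets of several methods on
#' the same sample when no ground truth exists. For method A compared
#' against k other methods, let \code{overlap_total} be the sum over the
#' other methods B of the number of A's calls that overlap at least one
#' call of B (status-agnostic single-base overlap by default). Then
#' \deqn{m_{cnv} = \mathrm{overlap\_total} / k, \quad
#'       m'_{cnv} = \mathrm{overlap\_total} / n_{detected}, \quad
#'       ODS = m_{cnv} \cdot m'_{cnv}.}
#' A method agreeing perfectly with every other method on n calls scores
#' ODS = n; disjoint call sets score 0. A method with zero calls is
#' reported with ODS 0 (with a warning) rather than a division error.
#'
#' @param callSets named list (>= 2 elements) of GRanges or
#'   [CNVCalls-class] objects, one per method
#' @param minOverlapFraction required overlap as a fraction of the other
#'   method's call (default 0 = any single-base overlap)
#' @param denominator \code{"others"} (default) divides m_cnv by the
#'   number of other methods k; \code{"all"} divides by k + 1 for
#'   sensitivity analysis
#' @return data.frame with one row per method: nDetected, overlapTotal,
#'   mCnv, mCnvPrime, ods
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), width = 100))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(50, 900), width = 100))
#' odsCompare(list(A = a, B = b))
#' @export
odsCompare <- function(callSets, minOverlapFraction = 0,
                       denominator = c("others", "all")) {
    denominator <- match.arg(denominator)
    stopifnot(is.list(callSets), length(callSets) >= 2L)
    if (is.null(names(callSets)) || any(names(callSets) == ""))
        names(callSets) <- paste0("method", seq_along(callSets))
    callSets <- lapply(callSets, function(x)
        if (is(x, "CNVCalls")) x@calls else x)
    stopifnot(all(vapply(callSets, is, logical(1), "GRanges")))
    m <- length(callSets)
    k <- if (denominator == "others") m - 1L else m
    res <- lapply(names(callSets), function(a) {
        A <- callSets[[a]]
        nDet <- length(A)
        ovl <- 0L
        for (b in setdiff(names(callSets), a)) {
            B <- callSets[[b]]
            if (!length(A) || !length(B)) next
            hits <- findOverlaps(A, B)
            if (minOverlapFraction > 0) {
                qh <- S4Vectors::queryHits(hits)
                sh <- S4Vectors::subjectHits(hits)
                ow <- width(IRanges::pintersect(IRanges::ranges(A)[qh],
                                                IRanges::ranges(B)[sh]))
                keep <- ow >= minOverlapFraction * width(B)[sh]
                ovl <- ovl + length(unique(qh[keep]))
            } else {
                ovl <- ovl + length(unique(S4Vectors::queryHits(hits)))
            }
        }
        if (nDet == 0L) {
            warning("method '", a, "' has no calls; ODS reported as 0")
            data.frame(method = a, nDetected = 0L, overlapTotal = 0L,
                       mCnv = 0, mCnvPrime = 0, ods = 0)
        } else {
            mCnv <- ovl / k
            mPrime <- ovl / nDet
            data.frame(method = a, nDetected = nDet,
                       overlapTotal = as.integer(ovl),
                       mCnv = mCnv, mCnvPrime = mPrime, ods = mCnv * mPrime)
        }
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
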