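#' Exact fused-lasso (total-variation) smoothing of a read-depth vector
#'
#' Returns the exact minimiser of
#' \deqn{\tfrac12 \sum_i (y_i - \beta_i)^2 +
#'       \lambda \sum_i |\beta_{i+1} - \beta_i|}
#' computed by a direct taut-string style algorithm (no iterative
#' approximation). With \code{lambda = 0} the input is returned unchanged;
#' as \code{lambda} grows the fit approaches the mean of \code{y}.
#'
#' @param y finite numeric vector (one contiguous unmasked stretch)
#' @param lambda penalty weight, >= 0
#' @return numeric vector of fitted values, same length as \code{y}
#' @examples
#' fusedLassoFit(c(1, 1.1, 0.9, 5, 5.2), lambda = 0.5)
#' @export
fusedLassoFit <- function(y, lambda) {
    if (!is.numeric(y) || length(y) < 1L)
        stop("y must be a non-empty numeric vector")
    if (any(!is.finite(y)))
        stop("y contains non-finite values")
    if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
        lambda < 0)
        stop("lambda must be a single value >= 0")
    .tv1dCondat(as.numeric(y), as.numeric(lambda))
}

#' Default fused-lasso penalty from the data
#'
#' Universal-threshold style heuristic: \eqn{\lambda = \hat\sigma
#' \sqrt{2 \ln n}} with the robust first-difference noise estimate
#' \eqn{\hat\sigma = \mathrm{median}(|y_{i+1} - y_i|) / (0.9545
#' \sqrt 2)}. A constant vector gives \eqn{\hat\sigma = 0} and hence
#' \eqn{\lambda = 0}.
#'
#' @param y numeric vector, length >= 2
#' @return a single non-negative penalty value
#' @export
selectLambda <- function(y) {
    stopifnot(is.numeric(y), length(y) >= 2L)
    sigma <- stats::median(abs(diff(y))) / (0.9545 * sqrt(2))
    sigma * sqrt(2 * log(length(y)))
}

#' Merge fitted values into segments
#'
#' Converts per-stretch fused-lasso fits into a [SegmentSet-class]:
#' within each contiguous unmasked stretch, maximal runs of bins whose
#' adjacent fitted values differ by at most \code{mergeTol} become one
#' segment. The segment level is the mean fitted value of the run (the
#' common value when the run is exactly constant); \code{rdMean} is the
#' mean corrected read depth of the member bins. Masked gaps always
#' terminate segments.
#'
#' @param profile a [BinProfile-class] (corrected; used for coordinates
#'   and rdMean)
#' @param fitted list of numeric vectors, one per contiguous unmasked
#'   stretch in genomic order (as produced by [segmentProfile()]), or a
#'   single vector when there is one stretch
#' @param mergeTol absolute tolerance for merging adjacent fitted values
#'   (default 1e-8)
#' @return a [SegmentSet-class]
#' @export
extractSegments <- function(profile, fitted, mergeTol = 1e-8) {
    stopifnot(is(profile, "BinProfile"))
    if (!is.list(fitted)) fitted <- list(fitted)
    stretches <- .unmaskedStretches(profile)
    if (length(fitted) != length(stretches))
        stop("fitted has ", length(fitted), " stretches but the profile has ",
             length(stretches))
    gr <- profile@bins
    rd <- mcols(gr)$rd
    if (all(is.na(rd))) rd <- mcols(gr)$rdRaw
    chrAll <- as.character(seqnames(gr))
    parts <- vector("list", length(stretches))
    for (s in seq_along(stretches)) {
        idx <- stretches[[s]]
        f <- fitted[[s]]
        if (length(f) != length(idx))
            stop("fitted stretch ", s, " has length ", length(f),
                 " but the stretch has ", length(idx), " bins")
        run <- cumsum(c(1L, as.integer(abs(diff(f)) > mergeTol)))
        first <- which(!duplicated(run))
        last <- c(first[-1L] - 1L, length(f))
        parts[[s]] <- data.frame(
            chrom = chrAll[idx[first]],
            start = start(gr)[idx[first]],
            end = end(gr)[idx[last]],
            level = as.numeric(rowsum(f, run)) / (last - first + 1L),
            rdMean = as.numeric(rowsum(rd[idx], run)) / (last - first + 1L),
            nBins = last - first + 1L,
            firstBin = idx[first],
            lastBin = idx[last])
    }
    df <- do.call(rbind, parts)
    seg <- GRanges(df$chrom, IRanges(df$start, df$end),
                   level = df$level, rdMean = df$rdMean,
                   nBins = as.integer(df$nBins),
                   firstBin = as.integer(df$firstBin),
                   lastBin = as.integer(df$lastBin))
    new("SegmentSet", segments = seg)
}

# maximal runs of consecutive unmasked bins within one chromosome,
# as a list of bin-index vectors in genomic order
.unmaskedStretches <- function(profile) {
    gr <- profile@bins
    mask <- mcols(gr)$mask
    chr <- as.character(seqnames(gr))
    res <- list()
    n <- length(gr)
    i <- 1L
    while (i <= n) {
        if (mask[i]) { i <- i + 1L; next }
        j <- i
        while (j < n && !mask[j + 1L] && chr[j + 1L] == chr[i]) j <- j + 1L
        res[[length(res) + 1L]] <- i:j
        i <- j + 1L
    }
    res
}

#' Segment a corrected read-depth profile
#'
#' Runs the exact fused-lasso smoother over every contiguous unmasked
#' stretch of the profile and merges the piecewise-constant output into a
#' [SegmentSet-class]. One penalty \code{lambda} is used for all
#' stretches; by default it is \code{lambdaScale} times the
#' universal-threshold value estimated once from the concatenated
#' unmasked read-depth vector with [selectLambda()]. The default scale of
#' 1.5 smooths away the short spurious plateaus that heavy-tailed count
#' noise produces at the plain universal threshold, while leaving
#' copy-number events of 20+ bins intact.
#'
#' @param profile a [BinProfile-class]; the corrected rd is segmented
#'   when present, otherwise the raw rd
#' @param lambda fused-lasso penalty, or NULL to select automatically
#' @param lambdaScale multiplier applied to the automatic penalty
#'   (ignored when \code{lambda} is given)
#' @param mergeTol see [extractSegments()]
#' @return a [SegmentSet-class]
#' @export
segmentProfile <- function(profile, lambda = NULL, lambdaScale = 1.5,
                           mergeTol = 1e-8) {
    stopifnot(is(profile, "BinProfile"))
    rd <- mcols(profile@bins)$rd
    if (all(is.na(rd))) rd <- mcols(profile@bins)$rdRaw
    stretches <- .unmaskedStretches(profile)
    if (!length(stretches))
        stop("all bins are masked; nothing to segment")
    yAll <- rd[unlist(stretches)]
    if (is.null(lambda))
        lambda <- if (length(yAll) >= 2L) lambdaScale * selectLambda(yAll)
                  else 0
    fitted <- lapply(stretches, function(idx) fusedLassoFit(rd[idx], lambda))
    extractSegments(profile, fitted, mergeTol = mergeTol)
}
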