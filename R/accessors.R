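#' @rdname BinProfile-class
#' @aliases binSize binCounts gcContent readDepth binMask bins
#' @export
setMethod("binSize", "BinProfile", function(x) x@binSize)

#' @rdname BinProfile-class
#' @export
setMethod("binCounts", "BinProfile", function(x) mcols(x@bins)$count)

#' @rdname BinProfile-class
#' @export
setMethod("gcContent", "BinProfile", function(x) mcols(x@bins)$gc)

#' @rdname BinProfile-class
#' @export
setMethod("readDepth", "BinProfile", function(x, raw = FALSE) {
    if (raw) mcols(x@bins)$rdRaw else mcols(x@bins)$rd
})

#' @rdname BinProfile-class
#' @export
setMethod("binMask", "BinProfile", function(x) mcols(x@bins)$mask)

#' Bin ranges of a BinProfile
#'
#' @param x a BinProfile
#' @return the underlying GRanges, one range per bin.
#' @export
bins <- function(x) {
    stopifnot(is(x, "BinProfile"))
    x@bins
}

#' @rdname BinProfile-class
#' @export
setMethod("length", "BinProfile", function(x) length(x@bins))

setMethod("show", "BinProfile", function(object) {
    mc <- mcols(object@bins)
    nch <- length(unique(as.character(seqnames(object@bins))))
    cat("BinProfile:", length(object@bins), "bins of", object@binSize,
        "bp on", nch, "chromosome(s)\n")
    cat("  masked:", sum(mc$mask),
        " gc annotated:", if (all(is.na(mc$gc))) "no" else "yes",
        " gc-corrected:", if (all(is.na(mc$rd))) "no" else "yes", "\n")
})

#' @rdname SegmentSet-class
#' @aliases segLevels segBins segments
#' @export
setMethod("segLevels", "SegmentSet", function(x) mcols(x@segments)$level)

#' @rdname SegmentSet-class
#' @export
setMethod("segBins", "SegmentSet", function(x) mcols(x@segments)$nBins)

#' Segment ranges of a SegmentSet
#'
#' @param x a SegmentSet
#' @return the underlying GRanges, one range per segment.
#' @export
segmentRanges <- function(x) {
    stopifnot(is(x, "SegmentSet"))
    x@segments
}

#' @rdname SegmentSet-class
#' @export
setMethod("length", "SegmentSet", function(x) length(x@segments))

setMethod("show", "SegmentSet", function(object) {
    lv <- mcols(object@segments)$level
    cat("SegmentSet:", length(object@segments), "segments,",
        sum(mcols(object@segments)$nBins), "bins\n")
    if (length(lv))
        cat("  level range: [", format(min(lv), digits = 4), ",",
            format(max(lv), digits = 4), "]\n")
})

#' @rdname FeatureTable-class
#' @aliases localDensityValues minDistanceValues gammaRadius
#' @export
setMethod("localDensityValues", "FeatureTable", function(x) x@rho)

#' @rdname FeatureTable-class
#' @export
setMethod("minDistanceValues", "FeatureTable", function(x) x@delta)

#' @rdname FeatureTable-class
#' @export
setMethod("gammaRadius", "FeatureTable", function(x) x@gamma)

#' @rdname FeatureTable-class
#' @export
setMethod("length", "FeatureTable", function(x) length(x@rho))

#' Distance between two segments in RD-level space
#'
#' Segments are represented by their fitted read-depth level, so the
#' distance between segments i and j is \code{abs(levels[i] - levels[j])}:
#' symmetric, zero on the diagonal and zero iff the levels are equal.
#'
#' @param x a FeatureTable
#' @param i,j segment indices (vectorised, recycled)
#' @return numeric distances
#' @export
featureDistance <- function(x, i, j) {
    stopifnot(is(x, "FeatureTable"))
    abs(x@levels[i] - x@levels[j])
}

setMethod("show", "FeatureTable", function(object) {
    cat("FeatureTable:", length(object@rho), "segments, gamma =",
        format(object@gamma, digits = 4), "\n")
    cat("  rho range: [", min(object@rho), ",", max(object@rho), "]",
        " delta range: [", format(min(object@delta), digits = 4), ",",
        format(max(object@delta), digits = 4), "]\n")
})

setMethod("show", "NullModel", function(object) {
    cat("NullModel: bivariate Gaussian over (rho, delta)\n")
    cat("  mu    =", format(object@mu, digits = 5), "\n")
    cat("  sigma =", format(object@sigma[1, ], digits = 5), "/",
        format(object@sigma[2, ], digits = 5), "\n")
    if (object@ridge > 0) cat("  ridge =", object@ridge, "\n")
})

#' Call ranges of a CNVCalls object
#'
#' @param x a CNVCalls
#' @return the underlying GRanges with status, rd, pValue, nBins columns.
#' @export
callRanges <- function(x) {
    stopifnot(is(x, "CNVCalls"))
    x@calls
}

#' @rdname CNVCalls-class
#' @param x a CNVCalls
#' @export
setMethod("length", "CNVCalls", function(x) length(x@calls))

setMethod("show", "CNVCalls", function(object) {
    st <- as.character(mcols(object@calls)$status)
    cat("CNVCalls:", length(object@calls), "calls (",
        sum(st == "amplification"), "amplification,",
        sum(st == "deletion"), "deletion )\n")
    md <- metadata(object@calls)
    if (!is.null(md$alpha))
        cat("  alpha =", md$alpha, " baseline rd =",
            format(md$baselineRD, digits = 5), "\n")
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nBins, "bins x", object@binSize,
        "bp, base depth", object@baseDepth, "\n")
    cat("  purity =", object@purity, " gcBias =", object@gcBias,
        " dispersion =", object@dispersion, " seed =", object@seed, "\n")
    cat("  planted CNVs:", nrow(object@cnvSpec), "\n")
})
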