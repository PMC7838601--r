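#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges findOverlaps
#' @importFrom GenomeInfoDb seqnames
#' @importFrom IRanges IRanges ranges pintersect start end width
#' @importFrom stats median quantile dist cov mahalanobis weighted.mean rnorm rpois rnbinom pnorm setNames
#' @useDynLib densityCNV, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' BinProfile: a binned read-depth profile
#'
#' Holds per-bin read counts along one or more chromosomes at a fixed bin
#' size, together with the GC fraction of each bin's reference sequence,
#' the raw and GC-corrected read depth, and a mask flagging bins excluded
#' from analysis (assembly gaps, long zero-coverage runs).
#'
#' The bin ranges are stored as a \link[GenomicRanges]{GRanges} (0-based
#' half-open coordinates are used in all on-disk output; internally the
#' GRanges follows the usual 1-based convention). Bins within a chromosome
#' are contiguous, non-overlapping and sorted.
#'
#' @slot bins GRanges with metadata columns \code{count} (integer reads
#'   assigned to the bin), \code{gc} (GC fraction in [0,1], NA where
#'   unannotated or all-N), \code{rdRaw} (raw read depth; equals
#'   \code{count} since bins have constant width), \code{rd}
#'   (GC-corrected read depth; NA before correction) and \code{mask}
#'   (logical, TRUE = excluded).
#' @slot binSize integer bin width in bp.
#'
#' @seealso [readBinCounts()], [annotateGC()], [correctGCBias()],
#'   [maskLowQualityBins()]
#' @export
setClass("BinProfile",
    slots = c(bins = "GRanges", binSize = "integer"))

setValidity("BinProfile", function(object) {
    msg <- character()
    need <- c("count", "gc", "rdRaw", "rd", "mask")
    have <- names(mcols(object@bins))
    if (!all(need %in% have))
        msg <- c(msg, paste0("missing bin columns: ",
                             paste(setdiff(need, have), collapse = ", ")))
    else {
        mc <- mcols(object@bins)
        ok <- !mc$mask
        if (any(mc$count[ok] < 0, na.rm = TRUE))
            msg <- c(msg, "negative count in unmasked bin")
        gcv <- mc$gc[ok]
        if (any(!is.na(gcv) & (gcv < 0 | gcv > 1)))
            msg <- c(msg, "gc outside [0,1] in unmasked bin")
        sp <- split(GenomicRanges::start(object@bins),
                    as.character(GenomicRanges::seqnames(object@bins)))
        for (ch in names(sp)) {
            s <- sp[[ch]]
            if (is.unsorted(s, strictly = TRUE))
                msg <- c(msg, paste0("bins not sorted on ", ch))
            else if (length(s) > 1 &&
                     any(diff(s) != object@binSize))
                msg <- c(msg, paste0("bins not contiguous on ", ch))
        }
    }
    if (length(object@binSize) != 1L || is.na(object@binSize) ||
        object@binSize < 1L)
        msg <- c(msg, "binSize must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' SegmentSet: piecewise-constant segments of a read-depth profile
#'
#' The output of fused-lasso segmentation: maximal runs of contiguous
#' unmasked bins sharing one fitted read-depth level. Segments are the
#' unit of all downstream testing.
#'
#' @slot segments GRanges with metadata columns \code{level} (fitted
#'   piecewise-constant RD value), \code{rdMean} (mean corrected rd of
#'   member bins), \code{nBins} (member-bin count), \code{firstBin} and
#'   \code{lastBin} (indices into the originating BinProfile, inclusive).
#' @seealso [segmentProfile()], [extractSegments()]
#' @export
setClass("SegmentSet", slots = c(segments = "GRanges"))

setValidity("SegmentSet", function(object) {
    mc <- mcols(object@segments)
    need <- c("level", "rdMean", "nBins", "firstBin", "lastBin")
    if (!all(need %in% names(mc)))
        return(paste0("missing segment columns: ",
                      paste(setdiff(need, names(mc)), collapse = ", ")))
    if (length(object@segments) &&
        any(mc$nBins != mc$lastBin - mc$firstBin + 1L))
        return("nBins inconsistent with bin span")
    TRUE
})

#' FeatureTable: density-peak features per segment
#'
#' For each segment: the local density rho (number of other segments whose
#' RD-level distance is strictly below the radius gamma) and the minimum
#' distance delta (distance to the nearest segment earlier in the density
#' ordering; maximum distance over all segments for the density peak
#' itself). The deterministic density ordering is (rho descending, genomic
#' index ascending).
#'
#' @slot rho integer vector of local densities, each in 0..(n-1).
#' @slot delta numeric vector of minimum distances, >= 0.
#' @slot orderRank integer: position of each segment in the density
#'   ordering (1 = global density peak).
#' @slot gamma the neighbourhood radius used.
#' @slot levels numeric segment RD levels; pairwise distances are
#'   \code{abs(levels[i] - levels[j])} (see [featureDistance()]).
#' @seealso [dpFeatures()], [localDensity()], [minDistance()]
#' @export
setClass("FeatureTable",
    slots = c(rho = "integer", delta = "numeric", orderRank = "integer",
              gamma = "numeric", levels = "numeric"))

setValidity("FeatureTable", function(object) {
    n <- length(object@levels)
    msg <- character()
    if (length(object@rho) != n || length(object@delta) != n ||
        length(object@orderRank) != n)
        msg <- c(msg, "rho, delta, orderRank, levels must have equal length")
    else {
        if (any(object@rho < 0L | object@rho > n - 1L))
            msg <- c(msg, "rho outside 0..(n-1)")
        if (any(object@delta < 0))
            msg <- c(msg, "negative delta")
        if (!setequal(object@orderRank, seq_len(n)))
            msg <- c(msg, "orderRank is not a permutation of 1..n")
    }
    if (length(object@gamma) != 1L || object@gamma <= 0)
        msg <- c(msg, "gamma must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' NullModel: bivariate Gaussian null over (rho, delta)
#'
#' @slot mu length-2 mean vector (mean rho, mean delta).
#' @slot sigma 2x2 covariance matrix, symmetric positive-definite after
#'   optional ridge regularisation.
#' @slot ridge the ridge added to the diagonal (0 if none was needed).
#' @seealso [fitNull()], [pValues()]
#' @export
setClass("NullModel",
    slots = c(mu = "numeric", sigma = "matrix", ridge = "numeric"))

setValidity("NullModel", function(object) {
    if (length(object@mu) != 2L) return("mu must have length 2")
    if (!all(dim(object@sigma) == c(2L, 2L))) return("sigma must be 2x2")
    if (max(abs(object@sigma - t(object@sigma))) > 1e-8 * sum(diag(object@sigma)))
        return("sigma not symmetric")
    ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return("sigma not positive-definite")
    TRUE
})

#' CNVCalls: significant copy-number calls
#'
#' Genomic intervals declared as CNVs, with the segment read-depth level,
#' the p-value under the bivariate Gaussian null, the call status
#' (amplification or deletion relative to the baseline read depth) and the
#' number of bins supporting the call.
#'
#' @slot calls GRanges with metadata columns \code{status} (factor:
#'   \code{"amplification"} or \code{"deletion"}), \code{rd}, \code{pValue}
#'   and \code{nBins}. Run metadata (alpha, baseline rd, gamma, ...) is in
#'   \code{metadata(calls)}.
#' @seealso [callCNVs()], [assignTypes()], [writeCalls()]
#' @export
setClass("CNVCalls", slots = c(calls = "GRanges"))

setValidity("CNVCalls", function(object) {
    mc <- mcols(object@calls)
    need <- c("status", "rd", "pValue", "nBins")
    if (!all(need %in% names(mc)))
        return(paste0("missing call columns: ",
                      paste(setdiff(need, names(mc)), collapse = ", ")))
    if (length(object@calls)) {
        if (!all(as.character(mc$status) %in% c("amplification", "deletion")))
            return("status must be amplification or deletion")
        if (any(mc$pValue <= 0 | mc$pValue > 1))
            return("pValue outside (0,1]")
    }
    TRUE
})

#' SimConfig: configuration of the read-depth profile simulator
#'
#' @slot nBins number of bins on the single simulated chromosome.
#' @slot binSize bin width in bp.
#' @slot baseDepth expected reads per bin at the diploid state (copy
#'   number 2); see [coverageDepth()] for the coverage presets.
#' @slot purity tumour purity in (0, 1]: the fraction of tumour cells.
#' @slot cnvSpec data.frame with columns \code{startBin} (0-based),
#'   \code{lengthBins}, \code{copyNumber} (integer != 2); intervals must
#'   be disjoint and inside [0, nBins).
#' @slot gcBias amplitude of the smooth GC response curve (0 = none).
#' @slot dispersion negative-binomial overdispersion; 0 = Poisson.
#' @slot seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @seealso [simulateProfile()], [randomCNVSpec()]
#' @export
setClass("SimConfig",
    slots = c(nBins = "integer", binSize = "integer", baseDepth = "numeric",
              purity = "numeric", cnvSpec = "data.frame", gcBias = "numeric",
              dispersion = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
    if (object@binSize < 1L) msg <- c(msg, "binSize must be >= 1")
    if (object@baseDepth <= 0) msg <- c(msg, "baseDepth must be > 0")
    if (object@purity <= 0 || object@purity > 1)
        msg <- c(msg, "purity must be in (0, 1]")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    cs <- object@cnvSpec
    if (nrow(cs)) {
        need <- c("startBin", "lengthBins", "copyNumber")
        if (!all(need %in% names(cs)))
            return("cnvSpec needs columns startBin, lengthBins, copyNumber")
        if (any(cs$copyNumber == 2))
            msg <- c(msg, "cnvSpec copyNumber must differ from 2")
        if (any(cs$copyNumber < 0)) msg <- c(msg, "negative copyNumber")
        if (any(cs$lengthBins < 1)) msg <- c(msg, "lengthBins must be >= 1")
        if (any(cs$startBin < 0 | cs$startBin + cs$lengthBins > object@nBins))
            msg <- c(msg, "cnvSpec interval outside [0, nBins)")
        o <- order(cs$startBin)
        s <- cs$startBin[o]; e <- s + cs$lengthBins[o]
        if (nrow(cs) > 1 && any(s[-1] < e[-nrow(cs)]))
            msg <- c(msg, "cnvSpec intervals overlap")
    }
    if (length(msg)) msg else TRUE
})
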