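#' @rdname BinProfile-class
#' @param x a BinProfile
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinProfile-class
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname BinProfile-class
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname BinProfile-class
#' @param raw logical; return the uncorrected read depth?
#' @export
setGeneric("readDepth", function(x, raw = FALSE) standardGeneric("readDepth"))

#' @rdname BinProfile-class
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname SegmentSet-class
#' @param x a SegmentSet
#' @export
setGeneric("segLevels", function(x) standardGeneric("segLevels"))

#' @rdname SegmentSet-class
#' @export
setGeneric("segBins", function(x) standardGeneric("segBins"))

#' @rdname FeatureTable-class
#' @param x a FeatureTable
#' @export
setGeneric("localDensityValues", function(x) standardGeneric("localDensityValues"))

#' @rdname FeatureTable-class
#' @export
setGeneric("minDistanceValues", function(x) standardGeneric("minDistanceValues"))

#' @rdname FeatureTable-class
#' @export
setGeneric("gammaRadius", function(x) standardGeneric("gammaRadius"))
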