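#' Run the full CNV-calling pipeline on a read-depth profile
#'
#' Executes the four-stage workflow on one sample: (I) build and clean
#' the binned read-depth profile (GC annotation if a reference is given,
#' median-stratum GC correction, masking of N-heavy bins and long
#' zero-coverage runs); (II) fused-lasso segmentation into
#' piecewise-constant segments; (III) density-peak features (rho, delta)
#' per segment; (IV) bivariate Gaussian null test, declaration at alpha
#' and amplification/deletion typing against the cluster-centre baseline.
#'
#' The run is deterministic given the inputs and parameters.
#'
#' @param input a [BinProfile-class], or a path to a BAM file / count
#'   table accepted by [readBinCounts()]
#' @param reference optional FASTA path for GC annotation (required for
#'   BAM input when GC correction is wanted and the table has no gc)
#' @param binSize bin width for BAM input
#' @param chroms optional chromosome subset for BAM input
#' @param alpha significance level for declaring CNVs (default 0.005)
#' @param lambda fused-lasso penalty; NULL selects it from the data
#' @param lambdaScale multiplier on the automatic penalty; see
#'   [segmentProfile()]
#' @param gamma density-peak radius; NULL selects it from the distances
#' @param neighborFraction quantile used when selecting gamma
#' @param gcBinWidth,minBinsPerStratum GC-correction strata parameters
#' @param zeroRunMin mask runs of at least this many zero-count bins
#' @param mergeTol tolerance for merging equal fitted levels
#' @param correctGC logical: run GC correction? (needs gc annotation)
#' @param verbose print a per-stage log?
#' @return a [CNVCalls-class]; run parameters and summary statistics
#'   (n segments, gamma, mu, sigma, baseline rd, lambda, alpha) are in
#'   \code{metadata(callRanges(x))}
#' @examples
#' cfg <- simConfig(nBins = 5000, purity = 1, dispersion = 0,
#'                  cnvSpec = data.frame(startBin = 1000, lengthBins = 50,
#'                                       copyNumber = 0))
#' sim <- simulateProfile(cfg)
#' calls <- callCNVs(sim$profile)
#' callRanges(calls)
#' @export
callCNVs <- function(input, reference = NULL, binSize = 1000L,
                     chroms = NULL, alpha = 0.005, lambda = NULL,
                     lambdaScale = 1.5, gamma = NULL, neighborFraction = 0.8,
                     gcBinWidth = 0.01, minBinsPerStratum = 20L,
                     zeroRunMin = 10L, mergeTol = 1e-8,
                     correctGC = TRUE, verbose = FALSE) {
    say <- function(...) if (verbose) message("[densityCNV] ", ...)
    profile <- if (is(input, "BinProfile")) input
               else readBinCounts(input, binSize = binSize, chroms = chroms)
    say("loaded ", length(profile), " bins of ", binSize(profile), " bp")
    if (!is.null(reference))
        profile <- annotateGC(profile, reference)
    profile <- maskLowQualityBins(profile, zeroRunMin = zeroRunMin)
    hasGC <- !all(is.na(gcContent(profile)))
    if (correctGC && hasGC) {
        profile <- correctGCBias(profile, gcBinWidth = gcBinWidth,
                                 minBinsPerStratum = minBinsPerStratum)
        say("GC correction done (", sum(binMask(profile)), " bins masked)")
    } else {
        mcols(profile@bins)$rd <- mcols(profile@bins)$rdRaw
        mcols(profile@bins)$rd[binMask(profile)] <- NA_real_
        say("GC correction skipped (no gc annotation)")
    }
    segs <- segmentProfile(profile, lambda = lambda,
                           lambdaScale = lambdaScale, mergeTol = mergeTol)
    say(length(segs), " segments")
    feats <- dpFeatures(segs, neighborFraction = neighborFraction,
                        gamma = gamma)
    model <- fitNull(feats, weights = segBins(segs))
    p <- pValues(feats, model)
    flagged <- declareCNVs(p, alpha = alpha)
    # the global density peak is the cluster centre and hence normal by
    # construction; its max-distance delta would otherwise mark it as an
    # outlier of the very null it anchors
    flagged <- setdiff(flagged, which(feats@orderRank == 1L))
    rb <- baselineRD(segs, feats)
    say(length(flagged), " significant segments at alpha = ", alpha,
        "; baseline rd = ", format(rb, digits = 5))
    calls <- assignTypes(segs, flagged, p, rb)
    gr <- calls@calls
    metadata(gr) <- list(alpha = alpha, baselineRD = rb,
                         gamma = gammaRadius(feats),
                         nSegments = length(segs),
                         nFlagged = length(flagged),
                         mu = model@mu, sigma = as.vector(model@sigma),
                         neighborFraction = neighborFraction)
    calls@calls <- gr
    calls
}

#' Fraction of segments flagged on a profile (null calibration helper)
#'
#' Runs the pipeline stages up to the significance test and returns the
#' fraction of segments with p below alpha. Used to check calibration on
#' CNV-free profiles, where the flagged fraction should be small.
#'
#' @inheritParams callCNVs
#' @return flagged-segment fraction (a single number)
#' @export
flaggedFraction <- function(input, alpha = 0.005, lambda = NULL,
                            gamma = NULL, neighborFraction = 0.8,
                            correctGC = TRUE) {
    calls <- callCNVs(input, alpha = alpha, lambda = lambda, gamma = gamma,
                      neighborFraction = neighborFraction,
                      correctGC = correctGC)
    md <- metadata(calls@calls)
    md$nFlagged / md$nSegments
}
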