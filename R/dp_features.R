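#' Pairwise distances between segments in RD-level space
#'
#' Each segment is represented by its fitted read-depth level, so the
#' distance between segments i and j is \code{abs(level[i] - level[j])}:
#' a metric on the real line, symmetric with zero diagonal, and zero iff
#' the levels are equal.
#'
#' @param segments a [SegmentSet-class] with at least 2 segments
#' @return a symmetric n x n distance matrix
#' @export
pairwiseDistances <- function(segments) {
    lv <- .segmentLevels(segments)
    n <- length(lv)
    if (n < 2L)
        stop("need at least 2 segments to define a density structure")
    abs(outer(lv, lv, "-"))
}

.segmentLevels <- function(segments) {
    if (is(segments, "SegmentSet")) mcols(segments@segments)$level
    else if (is.numeric(segments)) segments
    else stop("expected a SegmentSet or a numeric level vector")
}

#' Select the density-peak radius gamma
#'
#' Gamma is the \code{neighborFraction} quantile (linear-interpolation
#' quantile, type 7) of the n(n-1)/2 off-diagonal pairwise distances, so
#' that the mean neighbour count is roughly \code{neighborFraction} of n.
#' If that quantile is 0 (massive ties among levels), the smallest
#' positive distance is used instead.
#'
#' The default fraction of 0.8 makes the radius span the diploid
#' cluster: most pairwise distances are between normal segments, so a
#' high quantile tracks the cluster diameter and normal segments
#' saturate near the maximal local density, concentrating the null.
#' Small fractions (the 1--2\% rule of thumb used when density peaks are
#' sought for clustering) leave the local density position-dependent
#' inside the single diploid cluster and rob the outlier test of power.
#'
#' @param segments a [SegmentSet-class], or a numeric vector of segment
#'   RD levels
#' @param neighborFraction target mean-neighbour rate in (0, 1),
#'   default 0.8
#' @return a single positive radius
#' @export
selectGamma <- function(segments, neighborFraction = 0.8) {
    stopifnot(neighborFraction > 0, neighborFraction < 1)
    lv <- .segmentLevels(segments)
    if (length(lv) < 2L)
        stop("need at least 2 segments to define a density structure")
    d <- as.vector(stats::dist(lv, method = "manhattan"))
    g <- unname(stats::quantile(d, neighborFraction, type = 7))
    if (g <= 0) {
        pos <- d[d > 0]
        if (!length(pos))
            stop("all pairwise distances are zero; degenerate profile")
        g <- min(pos)
    }
    g
}

#' Local density of each segment
#'
#' The local density rho of segment i is the number of other segments
#' strictly within distance gamma:
#' \eqn{\rho_i = \#\{ j \ne i : d_{ij} < \gamma \}}
#' (the boundary \eqn{d_{ij} = \gamma} does not count).
#'
#' @param segments a [SegmentSet-class] or numeric level vector
#' @param gamma positive radius (see [selectGamma()])
#' @return integer vector of densities, each in 0..(n-1)
#' @export
localDensity <- function(segments, gamma) {
    stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
    lv <- .segmentLevels(segments)
    n <- length(lv)
    rho <- integer(n)
    chunk <- 2048L
    for (from in seq(1L, n, by = chunk)) {
        to <- min(from + chunk - 1L, n)
        dm <- abs(outer(lv[from:to], lv, "-"))
        rho[from:to] <- as.integer(rowSums(dm < gamma)) - 1L  # minus self
    }
    rho
}

#' Minimum distance to a denser segment
#'
#' Segments are ranked by the deterministic density ordering: rho
#' descending, genomic index ascending. The first segment in this
#' ordering (the global density peak) takes delta = max over all other
#' segments of d(i, j). Every other segment takes delta = min of d(i, j)
#' over the segments preceding it in the ordering, which equals the
#' minimum distance to a strictly denser segment whenever rho has no
#' ties, and resolves ties deterministically otherwise.
#'
#' @param segments a [SegmentSet-class] or numeric level vector
#' @param rho integer densities from [localDensity()]
#' @return list with \code{delta} (numeric) and \code{orderRank}
#'   (integer; 1 = density peak)
#' @export
minDistance <- function(segments, rho) {
    lv <- .segmentLevels(segments)
    n <- length(lv)
    stopifnot(length(rho) == n, n >= 2L)
    ord <- order(-rho, seq_len(n))
    delta <- numeric(n)
    peak <- ord[1L]
    delta[peak] <- max(abs(lv - lv[peak]))
    # growing prefix of "already placed" levels in density order
    prevLv <- numeric(n)
    prevLv[1L] <- lv[peak]
    for (k in 2:n) {
        i <- ord[k]
        delta[i] <- min(abs(prevLv[seq_len(k - 1L)] - lv[i]))
        prevLv[k] <- lv[i]
    }
    orderRank <- integer(n)
    orderRank[ord] <- seq_len(n)
    list(delta = delta, orderRank = orderRank)
}

#' Density-peak feature table for a segment set
#'
#' Computes the two density-peak statistics per segment -- local density
#' rho and minimum distance delta -- over the pairwise RD-level
#' distances, using radius gamma (selected from the distance
#' distribution unless given).
#'
#' CNV segments behave as outliers in this feature space: far from the
#' diploid bulk in RD level, they collect a small rho and a large delta.
#'
#' @param segments a [SegmentSet-class] with >= 2 segments
#' @param neighborFraction passed to [selectGamma()] when \code{gamma}
#'   is NULL
#' @param gamma radius override; NULL (default) selects it from the data
#' @return a [FeatureTable-class]
#' @examples
#' seg <- exampleSegments(c(10, 10.2, 9.9, 30), nBins = c(50, 40, 60, 5))
#' dpFeatures(seg)
#' @export
dpFeatures <- function(segments, neighborFraction = 0.8, gamma = NULL) {
    lv <- .segmentLevels(segments)
    if (length(lv) < 2L)
        stop("need at least 2 segments to define a density structure")
    if (is.null(gamma))
        gamma <- selectGamma(lv, neighborFraction)
    stopifnot(gamma > 0)
    rho <- localDensity(lv, gamma)
    md <- minDistance(lv, rho)
    new("FeatureTable", rho = rho, delta = md$delta,
        orderRank = md$orderRank, gamma = as.numeric(gamma), levels = lv)
}

#' Build a toy SegmentSet from levels (for examples and tests)
#'
#' Constructs a single-chromosome [SegmentSet-class] with the given
#' fitted levels and bin counts, with bins of 1 kb laid end to end.
#'
#' @param levels numeric segment RD levels
#' @param nBins integer bins per segment (recycled)
#' @param binSize bin width in bp
#' @param chrom chromosome name
#' @return a [SegmentSet-class]
#' @export
exampleSegments <- function(levels, nBins = 10L, binSize = 1000L,
                            chrom = "chr1") {
    nBins <- as.integer(rep_len(nBins, length(levels)))
    lastBin <- cumsum(nBins)
    firstBin <- lastBin - nBins + 1L
    seg <- GRanges(chrom,
                   IRanges(start = (firstBin - 1L) * binSize + 1L,
                           end = lastBin * binSize),
                   level = as.numeric(levels), rdMean = as.numeric(levels),
                   nBins = nBins, firstBin = firstBin, lastBin = lastBin)
    new("SegmentSet", segments = seg)
}

#' Write a feature dump TSV (segment coords, level, rho, delta)
#'
#' One row per segment with 0-based half-open coordinates; useful for
#' plotting the decision graph (delta against rho) externally.
#'
#' @param segments a [SegmentSet-class]
#' @param features the matching [FeatureTable-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeFeatures <- function(segments, features, path) {
    stopifnot(is(segments, "SegmentSet"), is(features, "FeatureTable"),
              length(features) == length(segments@segments))
    gr <- segments@segments
    lines <- sprintf("%s\t%d\t%d\t%.6g\t%d\t%.6g",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     mcols(gr)$level, features@rho, features@delta)
    writeLines(c("#chrom\tstart\tend\tlevel\trho\tdelta", lines), path)
    invisible(path)
}
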