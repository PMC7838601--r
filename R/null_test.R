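#' Fit the bivariate Gaussian null over (rho, delta)
#'
#' The null hypothesis is that a segment carries a normal copy number, in
#' which case its density-peak features sit in the bulk of the (rho,
#' delta) cloud. The null is the bivariate Gaussian with mu = sample mean
#' and Sigma = sample covariance (denominator n - 1) of the observed
#' features over all segments. If the smallest eigenvalue of Sigma is
#' below 1e-8 of its trace, a ridge of 1e-8 * trace is added to the
#' diagonal to keep it positive-definite.
#'
#' With \code{weights} (typically the segments' bin counts, as used by
#' [callCNVs()]), mu and Sigma become the weighted mean and unbiased
#' weighted covariance. Because CNV and transition segments are short,
#' bin weighting shrinks their share of the fit from their segment
#' fraction to their genome fraction, which keeps the null anchored on
#' the diploid bulk even when many events fragment into segments --
#' without it, a CNV-rich profile inflates Sigma and masks its own
#' outliers.
#'
#' @param features a [FeatureTable-class] with n >= 3 segments
#' @param weights optional non-negative weights, one per segment; NULL
#'   (default) gives every segment unit weight
#' @return a [NullModel-class]
#' @export
fitNull <- function(features, weights = NULL) {
    stopifnot(is(features, "FeatureTable"))
    n <- length(features@rho)
    if (n < 3L)
        stop("need at least 3 segments to fit the null distribution")
    x <- cbind(rho = as.numeric(features@rho), delta = features@delta)
    if (is.null(weights)) {
        mu <- colMeans(x)
        sigma <- stats::cov(x)
    } else {
        stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
        cw <- stats::cov.wt(x, wt = weights / sum(weights),
                            method = "unbiased")
        mu <- cw$center
        sigma <- cw$cov
    }
    tr <- sum(diag(sigma))
    if (tr <= 0) {
        zero <- c("rho", "delta")[diag(sigma) <= 0]
        stop("zero-variance feature(s): ", paste(zero, collapse = ", "),
             "; the null distribution is degenerate")
    }
    ridge <- 0
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8 * tr) {
        ridge <- 1e-8 * tr
        sigma <- sigma + diag(ridge, 2L)
    }
    if (any(diag(sigma) <= 0)) {
        zero <- c("rho", "delta")[diag(sigma) <= 0]
        stop("zero-variance feature after regularisation: ",
             paste(zero, collapse = ", "))
    }
    new("NullModel", mu = mu, sigma = sigma, ridge = ridge)
}

#' Null p-values for segment features
#'
#' For feature vector x with squared Mahalanobis distance
#' \eqn{m^2 = (x-\mu)^T \Sigma^{-1} (x-\mu)}, the p-value is the
#' probability mass of the bivariate Gaussian density region less
#' probable than x:
#' \deqn{p = \exp(-m^2/2)}
#' which equals the chi-squared (2 df) survival function at \eqn{m^2}.
#' p = 1 exactly at x = mu and decreases strictly in the Mahalanobis
#' distance.
#'
#' @param features a [FeatureTable-class]
#' @param model a [NullModel-class] from [fitNull()]
#' @return numeric p-values in (0, 1]
#' @export
pValues <- function(features, model) {
    stopifnot(is(features, "FeatureTable"), is(model, "NullModel"))
    x <- cbind(as.numeric(features@rho), features@delta)
    m2 <- stats::mahalanobis(x, model@mu, model@sigma)
    # exp(-m2/2) underflows to 0 for extreme outliers; keep p in (0, 1]
    pmax(exp(-m2 / 2), .Machine$double.xmin)
}

#' Declare CNV candidate segments
#'
#' Flags segments whose null p-value falls below the significance level
#' alpha. No multiple-testing correction is applied: alpha is a single
#' genome-wide cutoff on the per-segment p-value.
#'
#' @param p numeric p-values aligned with the segments
#' @param alpha significance level in (0, 1), default 0.005
#' @return integer indices of flagged segments, in genomic order
#' @export
declareCNVs <- function(p, alpha = 0.005) {
    stopifnot(is.numeric(p), alpha > 0, alpha <= 1)
    which(p < alpha)
}

#' Baseline read depth of the cluster centre
#'
#' The cluster centre is the segment with the largest local density
#' (ties broken toward the lowest genomic index): the density peak of
#' the diploid bulk. The baseline r_b is the bin-count-weighted mean
#' fitted level over all segments within distance gamma of the centre
#' (the centre itself included), so long normal segments dominate.
#'
#' @param segments a [SegmentSet-class]
#' @param features the matching [FeatureTable-class]
#' @return a single baseline read-depth value
#' @export
baselineRD <- function(segments, features) {
    stopifnot(is(segments, "SegmentSet"), is(features, "FeatureTable"))
    lv <- mcols(segments@segments)$level
    nb <- mcols(segments@segments)$nBins
    stopifnot(length(lv) == length(features@rho))
    centre <- which.max(features@rho)      # ties -> lowest index
    near <- abs(lv - lv[centre]) < features@gamma
    stats::weighted.mean(lv[near], nb[near])
}

#' Type flagged segments and build merged CNV calls
#'
#' Each flagged segment becomes a call: an amplification if its fitted
#' level exceeds the baseline r_b, a deletion otherwise (the tie level ==
#' r_b is typed deletion; a significant outlier cannot sit at the
#' baseline in practice). Adjacent same-status calls separated by zero
#' unmasked bins are merged into one interval; the merged call keeps the
#' minimum p-value, the bin-weighted mean level and the summed bin count.
#'
#' @param segments a [SegmentSet-class]
#' @param flagged integer indices from [declareCNVs()]
#' @param p p-values aligned with segments
#' @param rb baseline read depth from [baselineRD()]
#' @return a [CNVCalls-class], sorted by (chrom, start)
#' @export
assignTypes <- function(segments, flagged, p, rb) {
    stopifnot(is(segments, "SegmentSet"))
    gr <- segments@segments
    empty <- GRanges()
    mcols(empty) <- DataFrame(
        status = factor(character(), levels = c("amplification", "deletion")),
        rd = numeric(), pValue = numeric(), nBins = integer())
    if (!length(flagged))
        return(new("CNVCalls", calls = empty))
    flagged <- sort(flagged)
    sub <- gr[flagged]
    status <- ifelse(mcols(sub)$level > rb, "amplification", "deletion")
    # merge runs of flagged segments that are consecutive in the segment
    # list, on the same chromosome, with no unmasked bin between them
    # (lastBin + 1 == next firstBin covers same-stretch adjacency; a
    # masked gap also leaves zero unmasked bins between the calls, in
    # which case the segments are consecutive in the set as well)
    chr <- as.character(seqnames(sub))
    consec <- c(FALSE,
                diff(flagged) == 1L &
                chr[-1] == chr[-length(chr)] &
                status[-1] == status[-length(status)])
    grp <- cumsum(!consec)
    idx <- split(seq_along(flagged), grp)
    rows <- lapply(idx, function(ii) {
        s <- sub[ii]
        data.frame(chrom = as.character(seqnames(s))[1],
                   start = min(start(s)), end = max(end(s)),
                   status = status[ii[1]],
                   rd = stats::weighted.mean(mcols(s)$level, mcols(s)$nBins),
                   pValue = min(p[flagged[ii]]),
                   nBins = sum(mcols(s)$nBins))
    })
    df <- do.call(rbind, rows)
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    calls <- GRanges(df$chrom, IRanges(df$start, df$end),
                     status = factor(df$status,
                                     levels = c("amplification", "deletion")),
                     rd = df$rd, pValue = df$pValue,
                     nBins = as.integer(df$nBins))
    new("CNVCalls", calls = calls)
}

#' Write CNV calls as BED-like TSV
#'
#' Columns: chrom, start, end (0-based half-open), status, rd, p_value,
#' n_bins. A reproducibility header records the package version and the
#' run parameters stored in the call metadata.
#'
#' @param calls a [CNVCalls-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCalls <- function(calls, path) {
    stopifnot(is(calls, "CNVCalls"))
    gr <- calls@calls
    md <- metadata(gr)
    hdr <- c(sprintf("##densityCNV=%s",
                     as.character(utils::packageVersion("densityCNV"))),
             if (length(md))
                 sprintf("##%s=%s", names(md),
                         vapply(md, function(v)
                             paste(format(v, digits = 10), collapse = ","),
                             character(1))),
             "#chrom\tstart\tend\tstatus\trd\tp_value\tn_bins")
    lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%.6g\t%d",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     as.character(mcols(gr)$status), mcols(gr)$rd,
                     mcols(gr)$pValue, mcols(gr)$nBins)
    writeLines(c(hdr, lines), path)
    invisible(path)
}
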