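suppressPackageStartupMessages(library(GenomicRanges))

# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written without reference to the package
# internals (plain loops and matrices) so tests compare two routes.

# objective of the fused-lasso / total-variation problem
tvObjective <- function(y, b, lam) {
    0.5 * sum((y - b)^2) + lam * sum(abs(diff(b)))
}

# Exact global minimiser by exhaustive enumeration, valid for small n.
# Every candidate optimum is piecewise constant; for each partition of
# 1..n into contiguous blocks and each sign pattern of the between-block
# jumps, stationarity fixes the block values in closed form. The true
# optimum is one of these candidates, and every candidate is feasible,
# so the minimum candidate objective is the global optimum.
tvBruteForce <- function(y, lam) {
    n <- length(y)
    if (n == 1L || lam == 0) return(tvObjective(y, y, lam))
    signsCache <- lapply(seq_len(n - 1L), function(m1)
        as.matrix(expand.grid(rep(list(c(-1, 1)), m1))))
    best <- Inf
    for (mask in 0:(2^(n - 1L) - 1L)) {
        cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0)
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, n)
        m <- length(starts)
        nk <- ends - starts + 1L
        ybar <- vapply(seq_len(m), function(k) mean(y[starts[k]:ends[k]]), 0)
        if (m == 1L) {
            best <- min(best, tvObjective(y, rep(ybar, n), lam))
            next
        }
        signs <- signsCache[[m - 1L]]
        sPrev <- cbind(0, signs)
        sNext <- cbind(signs, 0)
        # beta_k = ybar_k - lam * (sigma_{k-1} - sigma_k) / n_k
        beta <- matrix(ybar, nrow(signs), m, byrow = TRUE) -
            lam * (sPrev - sNext) / matrix(nk, nrow(signs), m, byrow = TRUE)
        full <- beta[, rep(seq_len(m), nk), drop = FALSE]
        quad <- 0.5 * rowSums((matrix(y, nrow(full), n, byrow = TRUE) - full)^2)
        tv <- lam * rowSums(abs(beta[, -1L, drop = FALSE] -
                                beta[, -m, drop = FALSE]))
        best <- min(best, min(quad + tv))
    }
    best
}

# brute-force density-peak features: O(n^2) double loop straight from
# the definitions (strict d < gamma; ordering rho desc, index asc)
dpBruteForce <- function(levels, gamma) {
    n <- length(levels)
    d <- abs(outer(levels, levels, "-"))
    rho <- integer(n)
    for (i in seq_len(n))
        rho[i] <- sum(d[i, -i] < gamma)
    ord <- order(-rho, seq_len(n))
    delta <- numeric(n)
    for (pos in seq_len(n)) {
        i <- ord[pos]
        delta[i] <- if (pos == 1L) max(d[i, -i])
                    else min(d[i, ord[seq_len(pos - 1L)]])
    }
    list(rho = rho, delta = delta)
}

# literal transcription of the strictly-denser rule (defined only when
# rho has no ties below the top)
dpLiteralDelta <- function(levels, rho) {
    n <- length(levels)
    d <- abs(outer(levels, levels, "-"))
    delta <- numeric(n)
    top <- which(rho == max(rho))[1]
    for (i in seq_len(n)) {
        denser <- which(rho > rho[i])
        delta[i] <- if (i == top) max(d[i, -i])
                    else if (length(denser)) min(d[i, denser])
                    else NA_real_   # undefined under a tied maximum
    }
    delta
}

# minimal SAM text -> sorted, indexed BAM in tempdir
# reads: data.frame(pos, flag); all 50 bp on the one contig
writeToyBam <- function(reads, chromLen = 10000L, chrom = "chr1") {
    sam <- tempfile(fileext = ".sam")
    seq50 <- strrep("A", 50)
    qual50 <- strrep("I", 50)
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromLen))
    o <- order(reads$pos)
    body <- sprintf("r%03d\t%d\t%s\t%d\t60\t50M\t*\t0\t0\t%s\t%s",
                    seq_len(nrow(reads)), reads$flag[o], chrom,
                    reads$pos[o], seq50, qual50)
    writeLines(c(hdr, body), sam)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    bam
}

# small FASTA with given sequences; returns path
writeToyFasta <- function(seqs) {
    fa <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(names(seqs), function(nm)
        c(paste0(">", nm), seqs[[nm]]))), fa)
    fa
}

# hand-rolled FeatureTable for unit tests of the null model
makeFeatures <- function(rho, delta, gamma = 1, levels = NULL) {
    n <- length(rho)
    if (is.null(levels)) levels <- as.numeric(seq_len(n))
    ord <- order(-rho, seq_len(n))
    orderRank <- integer(n)
    orderRank[ord] <- seq_len(n)
    new("FeatureTable", rho = as.integer(rho), delta = as.numeric(delta),
        orderRank = orderRank, gamma = gamma, levels = levels)
}
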