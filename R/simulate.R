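# run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    code
}

#' Expected reads per bin for a given sequencing coverage
#'
#' With read length 100 bp, a coverage of c x over bins of width w bp
#' gives c * w / 100 expected reads per diploid bin; the 4x and 6x
#' presets over 1 kb bins are 40 and 60 reads per bin.
#'
#' @param coverage sequencing depth (e.g. 4 or 6)
#' @param binSize bin width in bp
#' @param readLength read length in bp (default 100)
#' @return expected reads per bin at copy number 2
#' @export
coverageDepth <- function(coverage, binSize = 1000L, readLength = 100L) {
    coverage * binSize / readLength
}

#' Construct a simulator configuration
#'
#' See [SimConfig-class] for the field semantics. The per-bin expected
#' count is
#' \deqn{\mu_i = \mathrm{baseDepth} \cdot
#'       [(1 - \mathrm{purity}) + \mathrm{purity} \cdot CN_i / 2]
#'       \cdot g(gc_i)}
#' with CN = 2 outside the planted CNVs, and \eqn{g(gc) = 1 +
#' \mathrm{gcBias}\,\sin(2\pi\,gc)} normalised to mean 1. Counts are
#' negative-binomial with the given overdispersion (Poisson when
#' \code{dispersion = 0}).
#'
#' @param nBins number of simulated bins
#' @param binSize bin width in bp
#' @param baseDepth expected reads per diploid bin; see [coverageDepth()]
#' @param purity tumour purity in (0, 1]
#' @param cnvSpec data.frame(startBin, lengthBins, copyNumber); see
#'   [randomCNVSpec()]
#' @param gcBias amplitude of the GC response curve (0 disables it)
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2); 0 = Poisson
#' @param seed RNG seed
#' @return a [SimConfig-class]
#' @export
simConfig <- function(nBins = 50000L, binSize = 1000L,
                      baseDepth = coverageDepth(6, binSize),
                      purity = 0.4,
                      cnvSpec = data.frame(startBin = integer(),
                                           lengthBins = integer(),
                                           copyNumber = integer()),
                      gcBias = 0, dispersion = 0.05, seed = 1L) {
    new("SimConfig", nBins = as.integer(nBins), binSize = as.integer(binSize),
        baseDepth = as.numeric(baseDepth), purity = as.numeric(purity),
        cnvSpec = as.data.frame(cnvSpec), gcBias = as.numeric(gcBias),
        dispersion = as.numeric(dispersion), seed = as.integer(seed))
}

#' Random disjoint CNV intervals for a simulation
#'
#' Draws \code{n} disjoint intervals with lengths uniform in
#' \code{lengthRange} bins and copy numbers sampled from
#' \code{copyNumbers}, separated by at least \code{minGap} bins so each
#' planted event is a distinct segment.
#'
#' @param n number of CNVs
#' @param nBins profile size in bins
#' @param lengthRange min/max CNV length in bins (default 20--100)
#' @param copyNumbers candidate integer copy numbers (none equal to 2)
#' @param minGap minimum separation between CNVs, in bins
#' @param seed RNG seed
#' @return a data.frame(startBin, lengthBins, copyNumber) usable as
#'   \code{cnvSpec}
#' @export
randomCNVSpec <- function(n = 20L, nBins = 50000L, lengthRange = c(20L, 100L),
                          copyNumbers = c(0L, 1L, 4L, 6L), minGap = 50L,
                          seed = 1L) {
    stopifnot(n >= 1, all(copyNumbers != 2L))
    .withSeed(seed, {
        lens <- sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
        cn <- sample(copyNumbers, n, replace = TRUE)
        # place n intervals with gaps by distributing the slack uniformly
        slack <- nBins - sum(lens) - (n + 1L) * minGap
        if (slack < 0)
            stop("nBins too small for ", n, " CNVs of these lengths")
        cuts <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
        starts <- minGap + cuts + cumsum(c(0L, lens[-n] + minGap))
        data.frame(startBin = as.integer(starts),
                   lengthBins = as.integer(lens),
                   copyNumber = as.integer(cn))
    })
}

#' Simulate a binned tumour read-depth profile with known truth
#'
#' Generates per-bin GC fractions from a smooth autocorrelated process in
#' [0.3, 0.7], forms the expected count per bin from the purity mixture
#' of tumour copy number and diploid stroma, applies the (optional)
#' sinusoidal GC response, and draws counts from a negative-binomial
#' (Poisson when dispersion is 0). Identical config (including seed)
#' gives bit-identical output.
#'
#' @param config a [SimConfig-class]
#' @param chrom chromosome name for the simulated contig
#' @return list with \code{profile} (a [BinProfile-class], gc annotated)
#'   and \code{truth} (GRanges of the planted CNVs with \code{copyNumber}
#'   and \code{status} = gain/loss columns)
#' @examples
#' cfg <- simConfig(nBins = 2000, purity = 1, dispersion = 0,
#'                  cnvSpec = data.frame(startBin = 500, lengthBins = 50,
#'                                       copyNumber = 0))
#' sim <- simulateProfile(cfg)
#' sim$profile
#' @export
simulateProfile <- function(config, chrom = "chrSim") {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nBins
    .withSeed(config@seed, {
        # smooth autocorrelated GC track in [0.3, 0.7]
        ar <- 0.99
        z <- as.numeric(stats::filter(stats::rnorm(n), ar,
                                      method = "recursive"))
        z <- z * sqrt(1 - ar^2)            # ~ unit marginal sd
        gc <- 0.3 + 0.4 * stats::pnorm(z)
        cn <- rep(2, n)
        cs <- config@cnvSpec
        if (nrow(cs))
            for (k in seq_len(nrow(cs))) {
                i <- (cs$startBin[k] + 1L):(cs$startBin[k] + cs$lengthBins[k])
                cn[i] <- cs$copyNumber[k]
            }
        g <- 1 + config@gcBias * sin(2 * pi * gc)
        g <- g / mean(g)
        mu <- config@baseDepth *
            ((1 - config@purity) + config@purity * cn / 2) * g
        counts <- if (config@dispersion == 0)
            stats::rpois(n, mu)
        else
            stats::rnbinom(n, mu = mu, size = 1 / config@dispersion)
        starts0 <- (seq_len(n) - 1L) * config@binSize
        gr <- GRanges(chrom, IRanges(start = starts0 + 1L,
                                     width = config@binSize),
                      count = as.integer(counts))
        profile <- .newBinProfile(gr, config@binSize, gc = gc)
        truth <- if (nrow(cs))
            GRanges(chrom,
                    IRanges(start = cs$startBin * config@binSize + 1L,
                            width = cs$lengthBins * config@binSize),
                    copyNumber = as.integer(cs$copyNumber),
                    status = factor(ifelse(cs$copyNumber > 2, "gain", "loss"),
                                    levels = c("gain", "loss")))
        else {
            tr <- GRanges()
            mcols(tr) <- DataFrame(copyNumber = integer(),
                                   status = factor(character(),
                                                   levels = c("gain", "loss")))
            tr
        }
        list(profile = profile, truth = truth)
    })
}

#' Write simulated truth intervals as BED
#'
#' Columns: chrom, start, end (0-based half-open), copy number, status.
#'
#' @param truth GRanges from [simulateProfile()]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeTruth <- function(truth, path) {
    lines <- sprintf("%s\t%d\t%d\t%d\t%s",
                     as.character(seqnames(truth)), start(truth) - 1L,
                     end(truth), mcols(truth)$copyNumber,
                     as.character(mcols(truth)$status))
    writeLines(c("#chrom\tstart\tend\tcopy_number\tstatus", lines), path)
    invisible(path)
}

#' Read a truth/call BED-like TSV into GRanges
#'
#' Accepts the files written by [writeTruth()] and [writeCalls()] (or any
#' TSV whose first three columns are chrom, 0-based start, end). A
#' status-like column named \code{status} (or the 4th/5th column matching
#' gain/loss/amplification/deletion) is carried through.
#'
#' @param path input path
#' @return GRanges, possibly with a \code{status} column
#' @export
readIntervals <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "##")]
    header <- NULL
    if (length(ln) && startsWith(ln[1], "#")) {
        header <- strsplit(sub("^#", "", ln[1]), "\t")[[1]]
        ln <- ln[-1]
    }
    if (!length(ln)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(status = character())
        return(gr)
    }
    tab <- utils::read.table(text = ln, sep = "\t", stringsAsFactors = FALSE)
    if (!is.null(header) && length(header) == ncol(tab)) names(tab) <- header
    gr <- GRanges(tab[[1]], IRanges(start = tab[[2]] + 1L, end = tab[[3]]))
    statusCol <- which(vapply(tab, function(col)
        is.character(col) && all(col %in% c("gain", "loss", "amplification",
                                            "deletion")), logical(1)))
    if (!is.null(header) && "status" %in% names(tab))
        mcols(gr)$status <- tab$status
    else if (length(statusCol))
        mcols(gr)$status <- tab[[statusCol[1]]]
    gr
}

# normalize gain/amplification and loss/deletion vocabularies
.callStatus <- function(x) {
    s <- as.character(x)
    s[s == "amplification"] <- "gain"
    s[s == "deletion"] <- "loss"
    s
}

#' Evaluate CNV calls against simulated truth
#'
#' A call is correct if it overlaps a truth interval of the same status
#' (gain/amplification vs loss/deletion) by at least
#' \code{minOverlapFraction} of the truth interval's width; the default 0
#' requires any overlap (> 0 bases). Precision is the fraction of calls
#' that are correct; sensitivity is the fraction of truth intervals
#' overlapped by at least one correct call (each truth interval matched
#' at most once); F1 is their harmonic mean (0 when both are 0). With no
#' calls and non-empty truth, precision is reported as 0 with a warning.
#'
#' @param calls a [CNVCalls-class] or GRanges with a status column
#' @param truth GRanges with \code{status} gain/loss
#' @param minOverlapFraction required overlap as a fraction of the truth
#'   interval (default 0 = any overlap)
#' @return list with \code{precision}, \code{sensitivity}, \code{f1},
#'   \code{nCalls}, \code{nTruth}, \code{nCorrectCalls},
#'   \code{nDetectedTruth}
#' @export
evaluateCalls <- function(calls, truth, minOverlapFraction = 0) {
    if (is(calls, "CNVCalls")) calls <- calls@calls
    stopifnot(is(calls, "GRanges"), is(truth, "GRanges"))
    nCalls <- length(calls)
    nTruth <- length(truth)
    if (nTruth == 0)
        stop("empty truth set")
    if (nCalls == 0) {
        warning("no calls; precision undefined, reported as 0")
        return(list(precision = 0, sensitivity = 0, f1 = 0,
                    nCalls = 0L, nTruth = nTruth, nCorrectCalls = 0L,
                    nDetectedTruth = 0L))
    }
    cs <- .callStatus(mcols(calls)$status)
    ts <- .callStatus(mcols(truth)$status)
    hits <- findOverlaps(calls, truth)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ow <- width(IRanges::pintersect(IRanges::ranges(calls)[qh],
                                    IRanges::ranges(truth)[sh]))
    good <- cs[qh] == ts[sh] &
        ow >= pmax(minOverlapFraction * width(truth)[sh], 1L)
    correctCalls <- unique(qh[good])
    detectedTruth <- unique(sh[good])
    precision <- length(correctCalls) / nCalls
    sensitivity <- length(detectedTruth) / nTruth
    f1 <- if (precision + sensitivity == 0) 0 else
        2 * precision * sensitivity / (precision + sensitivity)
    list(precision = precision, sensitivity = sensitivity, f1 = f1,
         nCalls = nCalls, nTruth = nTruth,
         nCorrectCalls = length(correctCalls),
         nDetectedTruth = length(detectedTruth))
}
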