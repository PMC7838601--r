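#' Load per-bin read counts from a BAM file or count table
#'
#' Builds a [BinProfile-class] covering each selected chromosome end to
#' end at a fixed bin size. From a BAM file, a read is assigned to the bin
#' containing its leftmost mapped base; unmapped, secondary and
#' duplicate-flagged reads are skipped. From a count-table TSV (dialect:
#' header \code{#chrom<TAB>start<TAB>count[<TAB>gc]}, 0-based bin starts)
#' the counts are taken as given.
#'
#' Bin width is constant, so the raw read depth of a bin is its count.
#'
#' @param source path to a coordinate-sorted, indexed BAM file, or to a
#'   count-table TSV written by [writeBinCounts()].
#' @param binSize bin width in bp (>= 100); ignored for TSV input, where
#'   the bin width is inferred from consecutive starts.
#' @param chroms optional character vector restricting the chromosomes
#'   loaded (BAM input only).
#' @return a [BinProfile-class]
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("#chrom\tstart\tcount\tgc",
#'              "chr1\t0\t5\t0.41", "chr1\t1000\t7\t0.47"), tsv)
#' readBinCounts(tsv)
#' @export
readBinCounts <- function(source, binSize = 1000L, chroms = NULL) {
    stopifnot(length(source) == 1L, is.character(source))
    if (!file.exists(source))
        stop("input file not found: ", source)
    if (grepl("\\.bam$", source, ignore.case = TRUE))
        .readBinCountsBam(source, as.integer(binSize), chroms)
    else
        .readBinCountsTsv(source)
}

.readBinCountsBam <- function(bam, binSize, chroms) {
    if (binSize < 100L)
        stop("binSize must be >= 100 bp")
    bai <- paste0(bam, ".bai")
    bai2 <- sub("\\.bam$", ".bai", bam)
    if (!file.exists(bai) && !file.exists(bai2))
        stop("BAM index not found for '", bam,
             "' (expected ", bai, "); index the file first")
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (is.null(chroms)) chroms <- names(hdr)
    missing <- setdiff(chroms, names(hdr))
    if (length(missing))
        stop("chromosome(s) absent from BAM header: ",
             paste(missing, collapse = ", "))
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE)
    grl <- lapply(chroms, function(ch) {
        len <- hdr[[ch]]
        nb <- as.integer(ceiling(len / binSize))
        param <- Rsamtools::ScanBamParam(flag = flag, what = c("pos"),
            which = GRanges(ch, IRanges(1L, len)))
        pos <- Rsamtools::scanBam(bam, param = param)[[1]]$pos
        idx <- (pos - 1L) %/% binSize           # 0-based bin index
        cnt <- tabulate(idx + 1L, nbins = nb)
        starts0 <- (seq_len(nb) - 1L) * binSize
        GRanges(ch, IRanges(start = starts0 + 1L,
                            end = pmin(starts0 + binSize, len)),
                count = as.integer(cnt))
    })
    gr <- do.call(c, grl)
    .newBinProfile(gr, binSize, gc = rep(NA_real_, length(gr)))
}

.readBinCountsTsv <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- startsWith(first, "#")
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#",
                             colClasses = NA, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
        stop("count table needs at least 3 columns (chrom, start, count)")
    names(tab)[1:3] <- c("chrom", "start", "count")
    gc <- if (ncol(tab) >= 4L) suppressWarnings(as.numeric(tab[[4L]]))
          else rep(NA_real_, nrow(tab))
    # bins must be sorted and non-overlapping within each chromosome
    binSize <- NA_integer_
    for (ch in unique(tab$chrom)) {
        s <- tab$start[tab$chrom == ch]
        if (length(s) > 1L) {
            d <- diff(s)
            bad <- which(d <= 0)
            if (length(bad))
                stop("count table rows unsorted or overlapping on ", ch,
                     ": first offending row has start ", s[bad[1] + 1],
                     " after ", s[bad[1]])
            binSize <- if (is.na(binSize)) as.integer(min(d)) else
                       min(binSize, as.integer(min(d)))
            if (any(d %% min(d) != 0) || any(d != min(d)))
                stop("count table bins not contiguous on ", ch,
                     ": first gap after start ", s[which(d != min(d))[1]])
        }
    }
    if (is.na(binSize)) binSize <- 1000L
    gr <- GRanges(tab$chrom,
                  IRanges(start = tab$start + 1L, width = binSize),
                  count = as.integer(tab$count))
    .newBinProfile(gr, binSize, gc = gc)
}

.newBinProfile <- function(gr, binSize, gc) {
    mcols(gr)$gc <- gc
    mcols(gr)$rdRaw <- as.numeric(mcols(gr)$count)
    mcols(gr)$rd <- rep(NA_real_, length(gr))
    mcols(gr)$mask <- rep(FALSE, length(gr))
    new("BinProfile", bins = gr, binSize = as.integer(binSize))
}

#' Write a BinProfile to the count-table TSV dialect
#'
#' Writes one row per bin with 0-based bin starts:
#' \code{#chrom<TAB>start<TAB>count<TAB>gc}. GC is written as \code{NA}
#' where unannotated. The mask and corrected rd are derived quantities
#' and are not stored.
#'
#' @param profile a [BinProfile-class]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
writeBinCounts <- function(profile, path) {
    stopifnot(is(profile, "BinProfile"))
    gr <- profile@bins
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(seqnames(gr)),
                     start(gr) - 1L,
                     mcols(gr)$count,
                     ifelse(is.na(mcols(gr)$gc), "NA",
                            sprintf("%.6f", mcols(gr)$gc)))
    writeLines(c("#chrom\tstart\tcount\tgc", lines), path)
    invisible(path)
}

#' Annotate bins with reference GC fraction
#'
#' Computes the GC fraction of each bin as (#G + #C)/(#A + #C + #G + #T)
#' over the bin's reference bases. Bins whose reference sequence is more
#' than 50\% N are masked (assembly gaps); their gc is NA.
#'
#' @param profile a [BinProfile-class]
#' @param reference path to a FASTA file (a .fai index is created if
#'   missing) covering every profile chromosome.
#' @return the profile with \code{gc} filled in and N-heavy bins masked.
#' @export
annotateGC <- function(profile, reference) {
    stopifnot(is(profile, "BinProfile"))
    if (!file.exists(reference))
        stop("reference FASTA not found: ", reference)
    if (!file.exists(paste0(reference, ".fai")))
        Rsamtools::indexFa(reference)
    fa <- Rsamtools::FaFile(reference)
    idx <- Rsamtools::scanFaIndex(fa)
    have <- as.character(seqnames(idx))
    wanted <- unique(as.character(seqnames(profile@bins)))
    missing <- setdiff(wanted, have)
    if (length(missing))
        stop("chromosome(s) absent from reference FASTA: ",
             paste(missing, collapse = ", "))
    gr <- profile@bins
    # clip bin ends to contig length for the fetch
    lens <- stats::setNames(end(idx), have)
    fetch <- GRanges(seqnames(gr),
                     IRanges(start(gr),
                             pmin(end(gr), lens[as.character(seqnames(gr))])))
    seqs <- Rsamtools::scanFa(fa, fetch)
    af <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
    acgt <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
    nN <- width(fetch) - acgt
    gc <- ifelse(acgt > 0,
                 rowSums(af[, c("G", "C"), drop = FALSE]) / acgt,
                 NA_real_)
    nHeavy <- nN > 0.5 * width(fetch)
    mcols(gr)$gc <- ifelse(nHeavy, NA_real_, gc)
    mcols(gr)$mask <- mcols(gr)$mask | nHeavy
    profile@bins <- gr
    validObject(profile)
    profile
}

#' Correct GC-content bias by median-stratum scaling
#'
#' Bins are stratified by GC fraction into strata of width
#' \code{gcBinWidth}. The corrected read depth of a bin is
#' \deqn{rd = rd_{raw} \cdot m / m_{gc}}
#' where \eqn{m} is the median raw read depth over all unmasked bins and
#' \eqn{m_{gc}} the median over unmasked bins in the bin's GC stratum.
#' Strata with fewer than \code{minBinsPerStratum} bins borrow the global
#' median (no correction); strata whose median is zero are masked. Bins
#' with no GC annotation are left uncorrected (rd = rdRaw).
#'
#' The correction preserves the global median and is scale-equivariant.
#'
#' @param profile a [BinProfile-class] with gc annotated
#' @param gcBinWidth stratum width on the GC fraction scale (default 0.01)
#' @param minBinsPerStratum minimum stratum occupancy for a
#'   stratum-specific correction (default 20)
#' @return the profile with \code{rd} filled in
#' @export
correctGCBias <- function(profile, gcBinWidth = 0.01, minBinsPerStratum = 20L) {
    stopifnot(is(profile, "BinProfile"), gcBinWidth > 0, gcBinWidth <= 1)
    gr <- profile@bins
    mc <- mcols(gr)
    ok <- !mc$mask
    if (!any(ok))
        stop("all bins are masked; nothing to correct")
    m <- stats::median(mc$rdRaw[ok])
    stratum <- pmin(floor(mc$gc / gcBinWidth),
                    floor(1 / gcBinWidth) - 1)  # gc = 1 falls in last stratum
    rd <- mc$rdRaw
    usable <- ok & !is.na(stratum)
    if (any(usable)) {
        sf <- factor(stratum[usable])
        med <- tapply(mc$rdRaw[usable], sf, stats::median)
        cnt <- tabulate(sf)
        names(cnt) <- levels(sf)
        mgc <- med[as.character(stratum[usable])]
        small <- cnt[as.character(stratum[usable])] < minBinsPerStratum
        mgc[small] <- m
        zero <- mgc == 0
        scaled <- mc$rdRaw[usable] * m / mgc
        scaled[zero] <- NA_real_
        rd[usable] <- scaled
        maskIdx <- which(usable)[zero]
        mc$mask[maskIdx] <- TRUE
    }
    mc$rd <- rd
    mc$rd[mc$mask] <- NA_real_
    mcols(gr) <- mc
    profile@bins <- gr
    validObject(profile)
    profile
}

#' Mask uncallable bins
#'
#' Masks every bin inside a run of at least \code{zeroRunMin} consecutive
#' zero-count bins (within one chromosome). Long zero runs are assembly
#' gaps or unmappable regions; left in, they would be called as
#' deletions. N-masked bins stay masked.
#'
#' @param profile a [BinProfile-class]
#' @param zeroRunMin minimum run length of zero-count bins to mask
#'   (default 10)
#' @return the profile with the mask updated
#' @export
maskLowQualityBins <- function(profile, zeroRunMin = 10L) {
    stopifnot(is(profile, "BinProfile"), zeroRunMin >= 1)
    gr <- profile@bins
    mc <- mcols(gr)
    chr <- as.character(seqnames(gr))
    for (ch in unique(chr)) {
        i <- which(chr == ch)
        z <- mc$count[i] == 0L
        r <- rle(z)
        hit <- r$values & r$lengths >= zeroRunMin
        if (any(hit)) {
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in which(hit))
                mc$mask[i[starts[k]:ends[k]]] <- TRUE
        }
    }
    mc$rd[mc$mask] <- NA_real_
    mcols(gr) <- mc
    profile@bins <- gr
    profile
}
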