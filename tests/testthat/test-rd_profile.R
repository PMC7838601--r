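test_that("reads are assigned to the bin containing their leftmost base", {
    # one mapped read at position 1500 on a 10 kb contig
    bam <- writeToyBam(data.frame(pos = 1500L, flag = 0L))
    bp <- readBinCounts(bam, binSize = 1000L)
    expect_s4_class(bp, "BinProfile")
    expect_equal(length(bp), 10L)
    cnt <- binCounts(bp)
    expect_equal(cnt[2], 1L)          # 0-based bin #1
    expect_equal(sum(cnt), 1L)
    expect_equal(readDepth(bp, raw = TRUE), as.numeric(cnt))
})

test_that("unmapped, secondary and duplicate reads are skipped and counts sum to kept reads", {
    reads <- data.frame(
        pos = c(100L, 2100L, 3100L, 4100L, 4200L),
        flag = c(0L, 4L, 256L, 1024L, 0L))   # mapped, unmapped, secondary, dup, mapped
    bam <- writeToyBam(reads)
    bp <- readBinCounts(bam, binSize = 1000L)
    expect_equal(sum(binCounts(bp)), 2L)
    expect_equal(binCounts(bp)[c(1, 5)], c(1L, 1L))
})

test_that("missing BAM index gives an error naming the file", {
    bam <- writeToyBam(data.frame(pos = 100L, flag = 0L))
    file.remove(paste0(bam, ".bai"))
    expect_error(readBinCounts(bam, binSize = 1000L), "index")
})

test_that("count-table TSV loads as given and rejects disorder", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount\tgc",
                 "chr1\t0\t5\t0.40", "chr1\t1000\t7\t0.50"), tsv)
    bp <- readBinCounts(tsv)
    expect_equal(length(bp), 2L)
    expect_equal(binCounts(bp), c(5L, 7L))
    expect_equal(gcContent(bp), c(0.40, 0.50))

    bad <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount", "chr1\t1000\t7", "chr1\t0\t5"), bad)
    expect_error(readBinCounts(bad), "unsorted|overlap")
    dup <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount", "chr1\t0\t7", "chr1\t0\t5"), dup)
    expect_error(readBinCounts(dup), "unsorted|overlap")
})

test_that("simulator output survives a TSV round trip", {
    cfg <- simConfig(nBins = 500, purity = 0.3, baseDepth = 40,
                     cnvSpec = data.frame(startBin = 100, lengthBins = 30,
                                          copyNumber = 4),
                     seed = 11)
    sim <- simulateProfile(cfg)
    tsv <- tempfile(fileext = ".tsv")
    writeBinCounts(sim$profile, tsv)
    back <- readBinCounts(tsv)
    expect_equal(binCounts(back), binCounts(sim$profile))
    expect_equal(gcContent(back), gcContent(sim$profile), tolerance = 1e-5)
    expect_equal(as.character(seqnames(bins(back))),
                 as.character(seqnames(bins(sim$profile))))
    expect_equal(start(bins(back)), start(bins(sim$profile)))
    expect_equal(binSize(back), binSize(sim$profile))
})

test_that("GC annotation computes base fractions and masks N-heavy bins", {
    seqs <- list(chrT = paste0(
        strrep("G", 500), strrep("C", 500),       # bin 1: gc = 1
        strrep("N", 600), strrep("A", 400),       # bin 2: 60% N -> masked
        paste0(strrep("G", 200), strrep("C", 200), strrep("A", 600))  # bin 3: 0.4
    ))
    fa <- writeToyFasta(seqs)
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount",
                 "chrT\t0\t10", "chrT\t1000\t10", "chrT\t2000\t10"), tsv)
    bp <- annotateGC(readBinCounts(tsv), fa)
    expect_equal(gcContent(bp)[1], 1.0)
    expect_true(binMask(bp)[2])
    expect_true(is.na(gcContent(bp)[2]))
    expect_equal(gcContent(bp)[3], 0.4)
    expect_error(annotateGC(readBinCounts(tsv), writeToyFasta(list(other = "ACGT"))),
                 "chrT")
})

test_that("GC correction is the median-stratum ratio and keeps invariants", {
    mkProfile <- function(counts, gc) {
        tsv <- tempfile(fileext = ".tsv")
        writeLines(c("#chrom\tstart\tcount\tgc",
                     sprintf("chr1\t%d\t%d\t%.4f",
                             (seq_along(counts) - 1L) * 1000L, counts, gc)),
                   tsv)
        readBinCounts(tsv)
    }
    # single stratum: correction is the identity
    bp <- mkProfile(c(4L, 8L, 12L), rep(0.455, 3))
    cor1 <- correctGCBias(bp, minBinsPerStratum = 1L)
    expect_equal(readDepth(cor1), readDepth(cor1, raw = TRUE))

    # two strata with medians 10 and 20, global median 15
    bp2 <- mkProfile(c(10L, 10L, 10L, 20L, 20L, 20L),
                     c(0.305, 0.305, 0.305, 0.605, 0.605, 0.605))
    cor2 <- correctGCBias(bp2, minBinsPerStratum = 1L)
    expect_equal(readDepth(cor2), c(15, 15, 15, 15, 15, 15))
    expect_equal(readDepth(cor2)[1] / readDepth(cor2, raw = TRUE)[1], 1.5)
    expect_equal(readDepth(cor2)[4] / readDepth(cor2, raw = TRUE)[4], 0.75)

    # sparse strata borrow the global median (no correction)
    cor3 <- correctGCBias(bp2, minBinsPerStratum = 10L)
    expect_equal(readDepth(cor3), readDepth(cor3, raw = TRUE))
})

test_that("GC correction preserves the global median and is scale-equivariant", {
    set.seed(42)
    n <- 2000
    gc <- runif(n, 0.3, 0.7)
    counts <- as.integer(rpois(n, 50 * (1 + 0.4 * sin(2 * pi * gc))))
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount\tgc",
                 sprintf("chr1\t%d\t%d\t%.4f", (seq_len(n) - 1L) * 1000L,
                         counts, gc)), tsv)
    bp <- correctGCBias(readBinCounts(tsv))
    ok <- !binMask(bp)
    expect_equal(median(readDepth(bp)[ok]),
                 median(readDepth(bp, raw = TRUE)[ok]), tolerance = 1e-9)

    # scaling all raw depths by c scales all corrected depths by c
    tsv2 <- tempfile(fileext = ".tsv")
    writeLines(c("#chrom\tstart\tcount\tgc",
                 sprintf("chr1\t%d\t%d\t%.4f", (seq_len(n) - 1L) * 1000L,
                         counts * 3L, gc)), tsv2)
    bp3 <- correctGCBias(readBinCounts(tsv2))
    expect_equal(readDepth(bp3)[ok], 3 * readDepth(bp)[ok], tolerance = 1e-12)
})

test_that("zero-run masking follows the run-length rule", {
    mk <- function(counts) {
        tsv <- tempfile(fileext = ".tsv")
        writeLines(c("#chrom\tstart\tcount",
                     sprintf("chr1\t%d\t%d", (seq_along(counts) - 1L) * 1000L,
                             counts)), tsv)
        readBinCounts(tsv)
    }
    m1 <- maskLowQualityBins(mk(c(5L, rep(0L, 15), 5L)), zeroRunMin = 10L)
    expect_equal(sum(binMask(m1)), 15L)
    expect_false(binMask(m1)[1])
    m2 <- maskLowQualityBins(mk(c(5L, rep(0L, 5), 5L, 5L)), zeroRunMin = 10L)
    expect_equal(sum(binMask(m2)), 0L)
    m3 <- maskLowQualityBins(mk(rep(c(0L, 5L), 10)), zeroRunMin = 2L)
    expect_equal(sum(binMask(m3)), 0L)
})
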