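test_that("simulation is deterministic and validates its CNV spec", {
    cfg <- simConfig(nBins = 1000, purity = 0.3, baseDepth = 40,
                     cnvSpec = data.frame(startBin = c(100, 400),
                                          lengthBins = c(50, 30),
                                          copyNumber = c(0, 4)),
                     seed = 77)
    a <- simulateProfile(cfg)
    b <- simulateProfile(cfg)
    expect_identical(binCounts(a$profile), binCounts(b$profile))
    expect_identical(gcContent(a$profile), gcContent(b$profile))
    expect_identical(a$truth, b$truth)
    expect_equal(length(a$profile), 1000L)
    expect_true(all(gcContent(a$profile) >= 0.3 & gcContent(a$profile) <= 0.7))

    expect_error(simConfig(nBins = 1000,
                           cnvSpec = data.frame(startBin = c(10, 30),
                                                lengthBins = c(40, 10),
                                                copyNumber = c(0, 4))),
                 "overlap")
    expect_error(simConfig(nBins = 1000,
                           cnvSpec = data.frame(startBin = 10,
                                                lengthBins = 10,
                                                copyNumber = 2)),
                 "copyNumber")
})

test_that("homozygous deletion at full purity yields zero counts", {
    cfg <- simConfig(nBins = 300, purity = 1, dispersion = 0, baseDepth = 60,
                     cnvSpec = data.frame(startBin = 100, lengthBins = 40,
                                          copyNumber = 0),
                     seed = 3)
    sim <- simulateProfile(cfg)
    inside <- 101:140
    expect_true(all(binCounts(sim$profile)[inside] == 0L))
    expect_true(all(binCounts(sim$profile)[-inside] > 0L))
})

test_that("expected counts follow the purity mixture", {
    # purity 0.4, CN 4 -> 1.4 x base depth; check the empirical mean over
    # seeded replicates against the binomial/Poisson standard error
    base <- 50
    mu <- base * (0.6 + 0.4 * 4 / 2)
    expect_equal(mu, 1.4 * base)
    tot <- 0; nTot <- 0
    for (s in 1:50) {
        cfg <- simConfig(nBins = 200, purity = 0.4, dispersion = 0,
                         baseDepth = base, gcBias = 0,
                         cnvSpec = data.frame(startBin = 50, lengthBins = 100,
                                              copyNumber = 4),
                         seed = s)
        sim <- simulateProfile(cfg)
        tot <- tot + sum(binCounts(sim$profile)[51:150])
        nTot <- nTot + 100
    }
    se <- sqrt(mu / nTot)
    expect_lt(abs(tot / nTot - mu), 3 * se)
})

test_that("truth intervals carry gain/loss status consistent with copy number", {
    cfg <- simConfig(nBins = 2000,
                     cnvSpec = data.frame(startBin = c(100, 500, 900, 1300),
                                          lengthBins = rep(50, 4),
                                          copyNumber = c(0, 1, 4, 6)),
                     seed = 1)
    tr <- simulateProfile(cfg)$truth
    expect_equal(as.character(mcols(tr)$status), c("loss", "loss",
                                                   "gain", "gain"))
    expect_equal(width(tr), rep(50000L, 4))
    out <- tempfile(fileext = ".bed")
    writeTruth(tr, out)
    back <- readIntervals(out)
    expect_equal(start(back), start(tr))
    expect_equal(mcols(back)$status, as.character(mcols(tr)$status))
})

test_that("random CNV specs are disjoint, bounded and reproducible", {
    for (s in 1:5) {
        sp <- randomCNVSpec(n = 20, nBins = 50000, seed = s)
        expect_equal(nrow(sp), 20L)
        expect_true(all(sp$lengthBins >= 20 & sp$lengthBins <= 100))
        expect_true(all(sp$copyNumber %in% c(0L, 1L, 4L, 6L)))
        o <- order(sp$startBin)
        gaps <- sp$startBin[o][-1] - (sp$startBin[o] + sp$lengthBins[o])[-20]
        expect_true(all(gaps >= 50))
        expect_true(all(sp$startBin >= 0 &
                        sp$startBin + sp$lengthBins <= 50000))
    }
    expect_identical(randomCNVSpec(seed = 9), randomCNVSpec(seed = 9))
})

test_that("call evaluation implements the overlap-matching definitions", {
    truth <- GRanges("chr1", IRanges(c(1001, 5001), width = 1000),
                     status = c("gain", "loss"))
    # calls identical to truth
    calls <- GRanges("chr1", IRanges(c(1001, 5001), width = 1000),
                     status = c("amplification", "deletion"))
    ev <- evaluateCalls(calls, truth)
    expect_equal(c(ev$precision, ev$sensitivity, ev$f1), c(1, 1, 1))

    # no calls
    noCalls <- GRanges()
    mcols(noCalls)$status <- character()
    expect_warning(ev0 <- evaluateCalls(noCalls, truth), "no calls")
    expect_equal(c(ev0$precision, ev0$sensitivity, ev0$f1), c(0, 0, 0))

    # 2 truth, 4 calls, 2 correct -> precision .5, sensitivity 1, F1 2/3
    calls4 <- GRanges("chr1",
                      IRanges(c(1001, 5001, 9001, 12001), width = 500),
                      status = c("gain", "loss", "gain", "loss"))
    ev4 <- evaluateCalls(calls4, truth)
    expect_equal(ev4$precision, 0.5)
    expect_equal(ev4$sensitivity, 1)
    expect_equal(ev4$f1, 2 / 3)

    # status must match for a call to count
    wrong <- GRanges("chr1", IRanges(1001, width = 1000), status = "loss")
    evW <- evaluateCalls(wrong, truth)
    expect_equal(evW$precision, 0)

    # reciprocal-fraction mode: a 10-base touch fails a 50% requirement
    touch <- GRanges("chr1", IRanges(1991, width = 1000), status = "gain")
    expect_equal(evaluateCalls(touch, truth)$precision, 1)
    expect_equal(evaluateCalls(touch, truth,
                               minOverlapFraction = 0.5)$precision, 0)
})

test_that("a truth interval is matched at most once for sensitivity", {
    truth <- GRanges("chr1", IRanges(1001, width = 1000), status = "gain")
    calls <- GRanges("chr1", IRanges(c(1001, 1501), width = 400),
                     status = c("gain", "gain"))
    ev <- evaluateCalls(calls, truth)
    expect_equal(ev$sensitivity, 1)
    expect_equal(ev$nDetectedTruth, 1L)
    expect_equal(ev$precision, 1)
})
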