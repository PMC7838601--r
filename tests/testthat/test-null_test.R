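test_that("null model is the sample mean and covariance of the features", {
    ft <- makeFeatures(rho = c(0L, 2L, 0L, 2L), delta = c(0, 0, 2, 2))
    m <- fitNull(ft)
    expect_equal(m@mu, c(rho = 1, delta = 1))
    expect_equal(unname(m@sigma), diag(c(4 / 3, 4 / 3)), tolerance = 1e-12)
    expect_equal(m@ridge, 0)

    set.seed(20)
    ft2 <- makeFeatures(rho = sample(0:25, 30, replace = TRUE),
                        delta = abs(rnorm(30)))
    m2 <- fitNull(ft2)
    expect_equal(unname(m2@mu),
                 c(mean(localDensityValues(ft2)), mean(minDistanceValues(ft2))),
                 tolerance = 1e-12)
    expect_error(fitNull(makeFeatures(c(0L, 1L), c(0, 1))), "at least 3")
})

test_that("degenerate features trigger the ridge or a named error, never NaN", {
    ftConst <- makeFeatures(rho = c(0L, 1L, 2L, 3L), delta = rep(1.5, 4))
    m <- fitNull(ftConst)             # delta variance 0 -> ridge path
    expect_gt(m@ridge, 0)
    ev <- eigen(m@sigma, only.values = TRUE)$values
    expect_true(all(ev > 0))
    p <- pValues(ftConst, m)
    expect_true(all(is.finite(p)))
    expect_error(fitNull(makeFeatures(rep(2L, 4), rep(1, 4))),
                 "zero-variance")
})

test_that("p-values are the Gaussian low-density tail in closed form", {
    ft <- makeFeatures(rho = c(0L, 2L, 0L, 2L), delta = c(0, 0, 2, 2))
    m <- new("NullModel", mu = c(0, 0), sigma = diag(2), ridge = 0)
    # p = 1 exactly at the mean (first row sits at mu)
    ftMu <- makeFeatures(rho = c(0L, 1L), delta = c(0, 3))
    expect_equal(pValues(ftMu, m)[1], 1)
    # m^2 = 2 ln 2 -> p = 1/2
    ftHalf <- makeFeatures(rho = c(0L, 1L), delta = c(sqrt(2 * log(2)), 0))
    expect_equal(pValues(ftHalf, m)[1], 0.5, tolerance = 1e-12)
    # identity covariance, offset (3,4): m^2 = 25
    ft34 <- makeFeatures(rho = c(3L, 0L, 1L, 2L), delta = c(4, 0, 0, 0))
    expect_equal(pValues(ft34, m)[1], exp(-12.5), tolerance = 1e-12)
    expect_equal(pValues(ft34, m)[1], pchisq(25, df = 2, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("p decreases strictly with Mahalanobis distance and stays in (0,1]", {
    m <- new("NullModel", mu = c(5, 1), sigma = diag(c(4, 0.25)), ridge = 0)
    r <- seq(0, 8, by = 0.25)
    ft <- makeFeatures(rho = as.integer(round(5 + 2 * r)), delta = 1 + 0.5 * r)
    p <- pValues(ft, m)
    expect_true(all(diff(p) < 0))
    expect_true(all(p > 0 & p <= 1))
})

test_that("declaration applies the alpha cutoff without correction", {
    expect_equal(declareCNVs(c(0.9, 0.001), alpha = 0.005), 2L)
    expect_equal(length(declareCNVs(c(0.9, 0.5, 0.1), alpha = 0.005)), 0L)
    expect_equal(declareCNVs(c(0.5, 0.99, 1), alpha = 1), c(1L, 2L))
})

test_that("baseline rd is the bin-weighted mean of the gamma-neighbourhood", {
    seg <- exampleSegments(c(10, 10.2, 30), nBins = c(100, 100, 10))
    ft <- dpFeatures(seg, gamma = 1)
    expect_equal(baselineRD(seg, ft), 10.1)
    # saturation: everything within gamma of the centre
    ftAll <- dpFeatures(seg, gamma = 100)
    expect_equal(baselineRD(seg, ftAll),
                 weighted.mean(c(10, 10.2, 30), c(100, 100, 10)))
    # isolated centre: neighbourhood is the centre alone
    seg2 <- exampleSegments(c(10, 20, 30.0, 30.4), nBins = c(5, 5, 5, 5))
    ft2 <- dpFeatures(seg2, gamma = 1)
    expect_equal(localDensityValues(ft2), c(0L, 0L, 1L, 1L))
    expect_equal(baselineRD(seg2, ft2),
                 weighted.mean(c(30.0, 30.4), c(5, 5)))
})

test_that("typing compares levels with the baseline and merges adjacent calls", {
    seg <- exampleSegments(c(2.1, 6.0, 14.0, 1.9, 2.2), nBins = 10)
    p <- c(1e-4, 0.9, 1e-4, 1e-4, 1e-3)
    calls <- assignTypes(seg, flagged = c(1L, 3L, 4L, 5L), p = p, rb = 6.0)
    gr <- callRanges(calls)
    expect_equal(as.character(mcols(gr)$status), c("deletion", "amplification",
                                                   "deletion"))
    # segments 4 and 5 are adjacent deletions -> merged, min p kept
    expect_equal(length(gr), 3L)
    expect_equal(mcols(gr)$nBins, c(10L, 10L, 20L))
    expect_equal(mcols(gr)$pValue[3], 1e-4)
    expect_equal(width(gr)[3], 20000L)
    # empty flag set gives an empty call object
    expect_equal(length(assignTypes(seg, integer(), p, 6)), 0L)
})

test_that("reflecting levels about the baseline swaps call labels", {
    lv <- c(10, 9.8, 25, 10.1, 3)
    rb <- 10
    seg <- exampleSegments(lv, nBins = 10)
    segR <- exampleSegments(2 * rb - lv, nBins = 10)
    p <- c(0.5, 0.6, 1e-4, 0.7, 1e-3)
    up <- assignTypes(seg, c(3L, 5L), p, rb)
    dn <- assignTypes(segR, c(3L, 5L), p, rb)
    expect_equal(as.character(mcols(callRanges(up))$status),
                 c("amplification", "deletion"))
    expect_equal(as.character(mcols(callRanges(dn))$status),
                 c("deletion", "amplification"))
    expect_equal(start(callRanges(up)), start(callRanges(dn)))
})

test_that("call files carry a reproducibility header", {
    seg <- exampleSegments(c(5, 20), nBins = 10)
    calls <- assignTypes(seg, 2L, c(0.5, 1e-5), rb = 5)
    out <- tempfile(fileext = ".bed")
    writeCalls(calls, out)
    ln <- readLines(out)
    expect_true(any(grepl("^##densityCNV=", ln)))
    expect_equal(sum(!startsWith(ln, "#")), 1L)
    back <- readIntervals(out)
    expect_equal(length(back), 1L)
    expect_equal(mcols(back)$status, "amplification")
})
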