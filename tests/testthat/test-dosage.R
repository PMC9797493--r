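test_that("binning averages per-base depth over full bin widths", {
    gl <- genomeLayout(c(chrA = 250000))
    pb <- data.frame(chrom = "chrA", pos = 1:250000, depth = 10)
    b <- binDepths(pb, gl, binSize = 1e5)
    expect_identical(length(b), 3L)
    expect_identical(GenomicRanges::width(b), c(1e5L, 1e5L, 5e4L))
    expect_equal(S4Vectors::mcols(b)$meanDepth, c(10, 10, 10))

    ## empty input: all bins zero
    b0 <- binDepths(pb[0, ], gl, binSize = 1e5)
    expect_equal(S4Vectors::mcols(b0)$meanDepth, c(0, 0, 0))

    ## depth 10 over the first 50 kb of a 100-kb bin averages to 5
    gl1 <- genomeLayout(c(chrA = 1e5))
    b1 <- binDepths(data.frame(chrom = "chrA", pos = 1:5e4, depth = 10),
                    gl1, binSize = 1e5)
    expect_equal(S4Vectors::mcols(b1)$meanDepth, 5)

    expect_error(binDepths(data.frame(chrom = "chrZ", pos = 1, depth = 1),
                           gl), "unknown chromosome")
    expect_error(binDepths(data.frame(chrom = "chrA", pos = 3e5, depth = 1),
                           gl), "outside")
})

test_that("RRD normalizes by the global per-bin median", {
    x <- rrdFromDepths(c(10, 10, 5))
    expect_equal(normalizationConstant(x), 10)
    expect_equal(S4Vectors::mcols(x)$rrd, c(1, 1, 0.5))

    xeq <- rrdFromDepths(rep(7, 12))
    expect_true(all(S4Vectors::mcols(xeq)$rrd == 1))

    expect_error(rrdFromDepths(rep(0, 5)), "cannot normalize")
})

test_that("median RRD is 1 by construction on random tables", {
    set.seed(42)
    for (i in 1:20) {
        d <- rpois(sample(5:200, 1), sample(10:80, 1))
        if (median(d) == 0) next
        x <- rrdFromDepths(d)
        expect_equal(median(S4Vectors::mcols(x)$rrd), 1)
        expect_equal(S4Vectors::mcols(x)$meanDepth /
                         normalizationConstant(x),
                     S4Vectors::mcols(x)$rrd)
    }
})

test_that("deletion calling scans runs of depressed bins", {
    x <- rrdTableFromRRD(c(1, 1, 0.6, 0.6, 0.6, 1))
    calls <- callDeletions(x, threshold = 0.8, minBins = 3)
    expect_identical(length(calls), 1L)
    expect_identical(S4Vectors::mcols(calls)$nBins, 3L)
    expect_identical(S4Vectors::mcols(calls)$sizeBp, 300000L)
    expect_equal(S4Vectors::mcols(calls)$meanRRD, 0.6)
    expect_equal(S4Vectors::mcols(calls)$mutantFraction, 0.8)
    ## bin-aligned 0-based interval [200000, 500000)
    expect_identical(GenomicRanges::start(calls), 200001L)
    expect_identical(GenomicRanges::end(calls), 500000L)

    expect_identical(length(callDeletions(rrdTableFromRRD(rep(1, 8)))), 0L)
    expect_error(callDeletions(x, threshold = 0), "threshold")
    expect_error(callDeletions(x, threshold = 1.2), "threshold")
})

test_that("gap tolerance bridges isolated above-threshold bins", {
    x <- rrdTableFromRRD(c(1, 0.6, 0.6, 0.6, 1, 0.6, 0.6, 0.6, 1))
    expect_identical(length(callDeletions(x, gap = 0)), 2L)
    merged <- callDeletions(x, gap = 1)
    expect_identical(length(merged), 1L)
    expect_identical(S4Vectors::mcols(merged)$nBins, 7L)
})

test_that("calls match brute-force run enumeration on small tables", {
    set.seed(99)
    for (i in 1:60) {
        n <- sample(3:20, 1)
        x <- rrdTableFromRRD(sample(c(0.6, 1), n, replace = TRUE,
                                    prob = c(0.4, 0.6)))
        minBins <- sample(1:3, 1)
        calls <- callDeletions(x, threshold = 0.8, minBins = minBins)
        oracle <- bruteForceRuns(S4Vectors::mcols(x)$rrd, 0.8, minBins)
        expect_identical(length(calls), length(oracle))
        for (j in seq_along(oracle)) {
            expect_identical(GenomicRanges::start(calls)[j],
                             as.integer((oracle[[j]]["start"] - 1) * 1e5 + 1))
            expect_identical(GenomicRanges::end(calls)[j],
                             as.integer(oracle[[j]]["end"] * 1e5))
        }
        ## sorted and non-overlapping
        if (length(calls) > 1) {
            expect_true(all(diff(GenomicRanges::start(calls)) > 0))
            expect_true(all(GenomicRanges::start(calls)[-1] >
                            GenomicRanges::end(calls)[-length(calls)]))
        }
    }
})

test_that("locus RRD averages overlapping bins, unweighted", {
    x <- rrdTableFromRRD(c(1, 0.65, 1, 1))
    gl <- genomeLayout(c(chrA = 4e5))
    inside <- genomicInterval("chrA", 120000, 150000, gl)
    expect_equal(locusRRD(x, inside), 0.65)
    straddle <- genomicInterval("chrA", 50000, 150000, gl)  # bins 1 + 2
    expect_equal(locusRRD(x, straddle), mean(c(1, 0.65)))
    uniform <- genomicInterval("chrA", 250000, 350000, gl)
    expect_equal(locusRRD(x, uniform), 1)
    expect_error(locusRRD(x, genomicInterval("chrQ", 0, 1e5)), "no bin")
})

test_that("mutant fraction inverts the mixture model with clamping", {
    expect_equal(estimateMutantFraction(1), 0)
    expect_equal(estimateMutantFraction(0.5), 1)
    expect_equal(estimateMutantFraction(0.65), 0.7)
    expect_equal(estimateMutantFraction(1.2), 0)   # clamped
    expect_equal(estimateMutantFraction(0.1), 1)   # clamped
    expect_error(estimateMutantFraction(-0.1), "non-negative")
})

test_that("simulation round trip recovers the mutant fraction within 0.05", {
    gl <- toyLayout()
    del <- genomicInterval("chrA", 4e5, 1.6e6, gl)  # 12 bins
    for (m in c(0.3, 0.5, 0.7, 0.9)) {
        b <- simulateBins(gl, del, mutantFraction = m, meanDepth = 30,
                          seed = round(1000 * m))
        x <- computeRRD(b)
        inDel <- IRanges::overlapsAny(x, del)
        est <- estimateMutantFraction(mean(S4Vectors::mcols(x)$rrd[inDel]))
        expect_lt(abs(est - m), 0.05)
    }
})
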