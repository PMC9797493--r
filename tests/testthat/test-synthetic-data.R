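test_that("simulators are bit-reproducible given a seed", {
    gl <- toyLayout()
    del <- genomicInterval("chrA", 5e5, 1.5e6, gl)
    expect_identical(simulateBins(gl, del, seed = 7),
                     simulateBins(gl, del, seed = 7))
    expect_identical(simulateQpcr("tt8", m = 0.7, seed = 7),
                     simulateQpcr("tt8", m = 0.7, seed = 7))
    expect_identical(simulateScreening(500, c(tt4 = 0.1, tt8 = 0.2), seed = 7),
                     simulateScreening(500, c(tt4 = 0.1, tt8 = 0.2), seed = 7))
    expect_identical(simulateSurvival(seed = 7), simulateSurvival(seed = 7))
    ## and the global RNG state is untouched
    set.seed(1); before <- .Random.seed
    simulateBins(gl, del, seed = 99)
    expect_identical(.Random.seed, before)
})

test_that("bin depths follow the mosaic copy-number mixture model", {
    gl <- toyLayout()
    ## null case: mean of all bin depths ~ lambda within 3 SE
    b0 <- simulateBins(gl, deletion = NULL, meanDepth = 40, seed = 1)
    d0 <- S4Vectors::mcols(b0)$meanDepth
    se <- sd(d0) / sqrt(length(d0))
    expect_lt(abs(mean(d0) - 40), 3 * se + 1e-9)

    ## full hemizygosity inside the deletion: mean ~ lambda/2
    del <- genomicInterval("chrA", 5e5, 1.5e6, gl)
    b1 <- simulateBins(gl, del, mutantFraction = 1, meanDepth = 40, seed = 2)
    inDel <- IRanges::overlapsAny(b1, del)
    expect_lt(abs(mean(S4Vectors::mcols(b1)$meanDepth[inDel]) - 20), 1)

    ## m = 0.7: deleted bins at (2 - 0.7)/2 = 0.65 of lambda
    b2 <- simulateBins(gl, del, mutantFraction = 0.7, meanDepth = 40,
                       seed = 3)
    expect_lt(abs(mean(S4Vectors::mcols(b2)$meanDepth[inDel]) - 0.65 * 40), 1)

    ## partial overlap scales copy number proportionally: empirical mean
    ## over replicates converges to lambda * c / 2
    half <- genomicInterval("chrB", 0, 5e4, gl)   # half of bin 1 on chrB
    m <- vapply(1:200, function(s) {
        b <- simulateBins(gl, half, mutantFraction = 1, meanDepth = 40,
                          seed = 1000 + s)
        S4Vectors::mcols(b)$meanDepth[
            as.character(GenomeInfoDb::seqnames(b)) == "chrB"][1L]
    }, numeric(1))
    expect_lt(abs(mean(m) - 40 * 1.5 / 2), 3 * sd(m) / sqrt(200) + 1e-9)

    expect_error(
        simulateBins(gl, genomicInterval("chrZ", 0, 1e5)), "outside")
})

test_that("noiseless qPCR simulation hits the comparative-Ct model exactly", {
    ctl <- simulateQpcr("control", ctNoiseSd = 0, baseCt = 25)
    expect_true(all(ctl$ct == 25))

    ## tt4-type at m = 0.75: TT4 copies 0.25 => Ct raised by exactly 2
    s4 <- simulateQpcr("tt4", m = 0.75, ctNoiseSd = 0, baseCt = 25)
    expect_equal(unique(s4$ct[s4$target == "TT4"]), 27)
    expect_equal(unique(s4$ct[s4$target == "TT8"]), 25)

    ## tt8-type at m = 0.7: TT8 Ct raised by log2(2/1.3)
    s8 <- simulateQpcr("tt8", m = 0.7, ctNoiseSd = 0, baseCt = 25)
    expect_equal(unique(s8$ct[s8$target == "TT8"]), 25 + log2(2 / 1.3))
    expect_equal(unique(s8$ct[s8$target == "TT4"]), 25)

    ## downstream: control vs control normalizes to ratio 1
    expect_equal(normalizedRatio(ctl, ctl)$ratio, 1)
})

test_that("screening simulation is multinomial over the three classes", {
    z <- simulateScreening(300, c(tt4 = 0, tt8 = 0), seed = 5)
    expect_identical(z@nMutant, 0L)
    expect_identical(z@nObserved, 300L)

    s <- simulateScreening(2588, c(tt4 = 2 / 2588, tt8 = 17 / 2588),
                           seed = 6)
    expect_lte(s@nMutant, 2588L)
    expect_identical(s@nTT4 + s@nTT8, s@nMutant)

    ## equal probabilities: class ratio -> 1 by the law of large numbers
    big <- simulateScreening(2e5, c(tt4 = 0.05, tt8 = 0.05), seed = 7)
    expect_lt(abs(big@nTT8 / big@nTT4 - 1), 0.1)
})

test_that("survival simulation respects the model's limits", {
    z <- simulateSurvival(D0 = 10, N = 20, doses = 0, nPerDose = 80,
                          seed = 8)
    expect_identical(z$n_survived, 80L)  # S(0) = 1
    hot <- simulateSurvival(D0 = 10, N = 20, doses = 500, nPerDose = 80,
                            seed = 9)
    expect_identical(hot$n_survived, 0L)
    ## survivors at an intermediate dose track S(D) = 1 - (1 - e^-3)^20
    mid <- simulateSurvival(D0 = 10, N = 20, doses = rep(30, 200),
                            nPerDose = 50, seed = 10)
    p <- 1 - (1 - exp(-3))^20
    expect_lt(abs(mean(mid$n_survived / 50) - p), 0.01)
})
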