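## brute-force pmf enumeration with choose(): the independent oracle
bruteBinom <- function(k, n, p0, alternative) {
    pmf <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
    switch(alternative,
        less = sum(pmf[0:k + 1]),
        greater = sum(pmf[k:n + 1]),
        two.sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

test_that("exact binomial test matches hand-computable cases", {
    expect_equal(binomTestExact(0, 1, 0.5)$p.value, 1)
    ## 2 of 19 under p0 = 0.5: minlike mass is 382/2^19
    expect_equal(binomTestExact(2, 19, 0.5)$p.value, 382 / 524288)
    ## length-weighted null, lower tail
    p0 <- 1789 / (1789 + 4643)
    expect_equal(binomTestExact(2, 19, p0, "less")$p.value,
                 bruteBinom(2, 19, p0, "less"))
    expect_gt(binomTestExact(2, 19, p0, "less")$p.value, 0.06)
    expect_lt(binomTestExact(2, 19, p0, "less")$p.value, 0.07)

    expect_error(binomTestExact(2, 19, 0), "p0")
    expect_error(binomTestExact(2, 19, 1), "p0")
    expect_error(binomTestExact(20, 19, 0.5))
})

test_that("exact test agrees with brute-force enumeration for n <= 25", {
    set.seed(7)
    for (n in 1:25) {
        p0 <- sample(c(0.1, 0.278, 0.5, 0.9), 1)
        for (k in unique(c(0, sample(0:n, min(4, n + 1)), n))) {
            for (alt in c("less", "greater", "two.sided")) {
                expect_equal(binomTestExact(k, n, p0, alt)$p.value,
                             bruteBinom(k, n, p0, alt),
                             tolerance = 1e-12)
            }
        }
    }
    ## and with the reference implementation's two-sided rule
    for (i in 1:25) {
        n <- sample(5:200, 1); k <- sample(0:n, 1)
        p0 <- runif(1, 0.05, 0.95)
        expect_equal(binomTestExact(k, n, p0)$p.value,
                     stats::binom.test(k, n, p0)$p.value)
    }
})

test_that("two-sided minlike p equals twice the smaller tail at p0 = 0.5", {
    for (n in c(5, 12, 19, 30)) {
        for (k in 0:n) {
            lo <- binomTestExact(k, n, 0.5, "less")$p.value
            hi <- binomTestExact(k, n, 0.5, "greater")$p.value
            expect_equal(binomTestExact(k, n, 0.5)$p.value,
                         min(1, 2 * min(lo, hi)))
        }
    }
})

test_that("one-sided lower p-values are monotone in k", {
    for (p0 in c(0.278, 0.5)) {
        pv <- vapply(0:19, function(k)
            binomTestExact(k, 19, p0, "less")$p.value, numeric(1))
        expect_true(all(diff(pv) > 0))
    }
})

test_that("length-weighted null and count summaries match their formulas", {
    expect_equal(round(lengthWeightedNull(1789, 4643), 2), 0.28)
    expect_equal(lengthWeightedNull(300, 300), 0.5)
    expect_equal(lengthWeightedNull(0, 100), 0)
    expect_error(lengthWeightedNull(0, 0), "zero")

    irr <- screeningCounts(2588, nTT4 = 2, nTT8 = 17)
    expect_equal(mutationFrequency(irr), 0.7)
    expect_equal(classRatio(irr), 8.5)
    ctl <- screeningCounts(430, 0, 0, group = "non-irradiated")
    expect_equal(mutationFrequency(ctl), 0)
    expect_error(classRatio(ctl), "undefined")
    expect_equal(mutationFrequency(screeningCounts(50, 30, 20)), 100)
    expect_equal(classRatio(screeningCounts(10, 1, 0)), 0)
    expect_error(mutationFrequency(screeningCounts(0, 0, 0)), "no plants")

    expect_error(screeningCounts(10, 8, 8), "exceed")
    expect_error(screeningCounts(10, -1, 2), "non-negative")
})
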