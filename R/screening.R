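#' Construct screening counts
#'
#' @param nObserved Plants screened.
#' @param nTT4,nTT8 Mutant plants per phenotype class.
#' @param group Population label.
#' @return A [ScreeningCounts-class] object (`nMutant = nTT4 + nTT8`).
#' @examples
#' screeningCounts(2588, nTT4 = 2, nTT8 = 17, group = "irradiated")
#' @export
screeningCounts <- function(nObserved, nTT4, nTT8, group = "irradiated") {
    new("ScreeningCounts", group = group,
        nObserved = as.integer(nObserved),
        nMutant = as.integer(nTT4) + as.integer(nTT8),
        nTT4 = as.integer(nTT4), nTT8 = as.integer(nTT8))
}

setMethod("show", "ScreeningCounts", function(object) {
    cat(sprintf(
        "ScreeningCounts [%s]: %d observed, %d mutant (tt4 %d, tt8 %d)\n",
        object@group, object@nObserved, object@nMutant,
        object@nTT4, object@nTT8))
})

#' Exact binomial test
#'
#' Exact tail-sum binomial test with no normal approximation. One-sided
#' p-values are the exact tails `P(X <= k)` (`"less"`) and `P(X >= k)`
#' (`"greater"`); the two-sided p-value uses the minimum-likelihood
#' ("minlike") rule: the sum of `P(X = j)` over all outcomes `j` whose
#' probability does not exceed that of the observed `k` (up to a 1e-7
#' relative tolerance against floating-point ties). Probabilities come
#' from the exact pmf (`dbinom`), accurate for `n` well beyond 1e4.
#'
#' @param k Observed successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability, strictly inside `(0, 1)`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return An object of class `"htest"` with the p-value and inputs.
#' @examples
#' binomTestExact(2, 19, 0.5)$p.value          # 382/2^19 ~ 7.3e-4
#' binomTestExact(2, 19, 1789/6432, "less")    # ~0.069
#' @export
binomTestExact <- function(k, n, p0 = 0.5,
                           alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L,
              k >= 0, n >= 1, k <= n, k == round(k), n == round(n))
    if (p0 <= 0 || p0 >= 1)
        stop("p0 must lie strictly inside (0, 1)")
    d <- dbinom(0:n, n, p0)
    pv <- switch(alternative,
        less = sum(d[seq_len(k + 1L)]),
        greater = sum(d[(k + 1L):(n + 1L)]),
        two.sided = sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
    pv <- min(1, pv)
    structure(list(
        statistic = c(k = k), parameter = c(n = n, p0 = p0),
        p.value = pv, alternative = alternative,
        method = "Exact binomial test (minlike two-sided)",
        data.name = sprintf("%d successes in %d trials", k, n)),
        class = "htest")
}

#' Gene-length-weighted null probability
#'
#' Under the assumption that mutation frequency is proportional to gene
#' length, the null probability that a mutation hits the target gene
#' rather than the other gene is `l_target / (l_target + l_other)` — e.g.
#' 1789/(1789+4643) = 0.278 (reported as 0.28) for a 1789-bp gene paired
#' with a 4643-bp gene.
#'
#' @param lTarget Target gene length in bp (0 allowed).
#' @param lOther Other gene length in bp.
#' @return The null probability.
#' @examples
#' lengthWeightedNull(1789, 4643)  # 0.278..., i.e. 0.28
#' @export
lengthWeightedNull <- function(lTarget, lOther) {
    stopifnot(lTarget >= 0, lOther >= 0)
    if (lTarget + lOther == 0)
        stop("gene lengths cannot both be zero")
    lTarget / (lTarget + lOther)
}

#' Mutation frequency of a screen
#'
#' Percentage of screened plants producing mutant seeds,
#' `100 * nMutant / nObserved`, reported to one decimal place.
#'
#' @param counts A [ScreeningCounts-class] object.
#' @return Percentage, rounded to one decimal.
#' @examples
#' mutationFrequency(screeningCounts(2588, 2, 17))  # 0.7
#' @export
mutationFrequency <- function(counts) {
    stopifnot(is(counts, "ScreeningCounts"))
    if (counts@nObserved == 0)
        stop("no plants observed")
    round(100 * counts@nMutant / counts@nObserved, 1)
}

#' tt8:tt4 mutant class ratio
#'
#' How many times more often the tt8 phenotype class was observed than
#' the tt4 class, `nTT8 / nTT4`.
#'
#' @param counts A [ScreeningCounts-class] object with `nTT4 > 0`.
#' @return The ratio.
#' @examples
#' classRatio(screeningCounts(2588, 2, 17))  # 8.5
#' @export
classRatio <- function(counts) {
    stopifnot(is(counts, "ScreeningCounts"))
    if (counts@nTT4 == 0)
        stop("class ratio undefined: no tt4-type mutants")
    counts@nTT8 / counts@nTT4
}
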