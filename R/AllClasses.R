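#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importFrom GenomicRanges GRanges granges tileGenome findOverlaps pintersect
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqlevels
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom stats dbinom pbinom rpois rnbinom rnorm rmultinom rbinom median
#'   lm coef sd setNames
#' @importFrom utils read.delim write.table
NULL

#' GenomeLayout: chromosome sizes, named loci and qPCR/amplicon targets
#'
#' A `GenomeLayout` holds the coordinate bookkeeping for a dosage analysis:
#' an ordered set of chromosomes with their lengths (a
#' [GenomeInfoDb::Seqinfo]), a set of named locus intervals (e.g. the
#' heterozygous marker genes `TT4` and `TT8`) and a set of named
#' amplicon/qPCR target intervals, both stored as [GenomicRanges::GRanges]
#' tied to that Seqinfo.
#'
#' Validity requires positive chromosome lengths, unique locus and target
#' names, and every interval to lie within its chromosome.
#'
#' @slot seqinfo A `Seqinfo` with the chromosome names and lengths.
#' @slot loci A named `GRanges` of locus intervals.
#' @slot ampliconTargets A named `GRanges` of PCR/qPCR target intervals.
#'
#' @seealso [genomeLayout()], [arabidopsisLayout()], [readGenomeLayout()]
#' @export
setClass("GenomeLayout",
    slots = c(
        seqinfo = "Seqinfo",
        loci = "GRanges",
        ampliconTargets = "GRanges"
    )
)

.validGenomeLayout <- function(object) {
    msg <- character()
    sl <- seqlengths(object@seqinfo)
    if (length(sl) == 0L)
        msg <- c(msg, "layout must contain at least one chromosome")
    if (anyNA(sl) || any(sl <= 0, na.rm = TRUE))
        msg <- c(msg, "all chromosome lengths must be positive")
    checkGr <- function(gr, what) {
        m <- character()
        nm <- names(gr)
        if (length(gr) > 0 && (is.null(nm) || anyNA(nm) || any(nm == "")))
            m <- c(m, sprintf("all %s must be named", what))
        if (anyDuplicated(nm))
            m <- c(m, sprintf("%s names must be unique", what))
        bad <- as.character(seqnames(gr)) %in% names(sl[!is.na(sl)]) == FALSE
        if (any(bad))
            m <- c(m, sprintf("%s on unknown chromosome: %s", what,
                              paste(nm[bad], collapse = ", ")))
        lim <- sl[as.character(seqnames(gr))]
        out <- !bad & (GenomicRanges::start(gr) < 1 |
                       GenomicRanges::end(gr) > lim)
        if (any(out, na.rm = TRUE))
            m <- c(m, sprintf("%s outside chromosome bounds: %s", what,
                              paste(nm[which(out)], collapse = ", ")))
        m
    }
    msg <- c(msg, checkGr(object@loci, "loci"),
             checkGr(object@ampliconTargets, "amplicon targets"))
    if (length(msg)) msg else TRUE
}
setValidity("GenomeLayout", .validGenomeLayout)

#' RRDTable: binned coverage with relative read depth
#'
#' An `RRDTable` extends [GenomicRanges::GRanges]: one range per genomic
#' bin, with metadata columns `meanDepth` (mean per-base read depth over
#' the bin) and `rrd` (relative read depth: `meanDepth` divided by the
#' median `meanDepth` over all bins of all chromosomes). The normalization
#' constant (that median) is kept in `metadata(x)$normalizationConstant`.
#'
#' Construct with [computeRRD()]; heterozygous deletions carried by a cell
#' fraction `m` appear as runs of bins with `rrd` near `1 - m/2`.
#'
#' @seealso [computeRRD()], [callDeletions()], [locusRRD()]
#' @export
setClass("RRDTable", contains = "GRanges")

setValidity("RRDTable", function(object) {
    msg <- character()
    mc <- mcols(object)
    for (col in c("meanDepth", "rrd")) {
        if (!col %in% colnames(mc))
            msg <- c(msg, sprintf("missing metadata column '%s'", col))
        else if (!is.numeric(mc[[col]]) || any(mc[[col]] < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("'%s' must be non-negative numeric", col))
    }
    k <- metadata(object)$normalizationConstant
    if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0)
        msg <- c(msg,
            "metadata(x)$normalizationConstant must be a positive scalar")
    if (length(msg)) msg else TRUE
})

#' ScreeningCounts: mutant-class counts from a seed-color screen
#'
#' Counts from screening a population of double heterozygous plants for
#' loss-of-heterozygosity seed phenotypes: number of plants observed,
#' number producing mutant (anthocyanin-less) seeds, and the split of the
#' mutants into the two phenotype classes (`tt4`-type pale yellow vs
#' `tt8`-type pale brown mature seeds).
#'
#' @slot group Label for the population (e.g. `"irradiated"`).
#' @slot nObserved Total plants screened.
#' @slot nMutant Plants with mutant seeds; must equal `nTT4 + nTT8`.
#' @slot nTT4,nTT8 Mutant plants per phenotype class.
#'
#' @seealso [screeningCounts()], [binomTestExact()], [mutationFrequency()]
#' @export
setClass("ScreeningCounts",
    slots = c(group = "character", nObserved = "integer",
              nMutant = "integer", nTT4 = "integer", nTT8 = "integer")
)

setValidity("ScreeningCounts", function(object) {
    msg <- character()
    v <- c(observed = object@nObserved, mutant = object@nMutant,
           tt4 = object@nTT4, tt8 = object@nTT8)
    if (anyNA(v) || any(v < 0))
        msg <- c(msg, "all counts must be non-negative")
    else {
        if (object@nTT4 + object@nTT8 != object@nMutant)
            msg <- c(msg, "nTT4 + nTT8 must equal nMutant")
        if (object@nMutant > object@nObserved)
            msg <- c(msg, "nMutant cannot exceed nObserved")
    }
    if (length(object@group) != 1L)
        msg <- c(msg, "group must be a single string")
    if (length(msg)) msg else TRUE
})

#' MultitargetFit: fitted single-hit multitarget survival curve
#'
#' Result of fitting the single-hit multitarget survival model
#' \deqn{S(D) = 1 - (1 - e^{-D/D_0})^N}
#' to dose-survival data: the per-target 1/e dose `D0` (Gy), the
#' extrapolation number `N`, the quasi-threshold ("shoulder") dose
#' `Dq = D0 ln N` (Gy) and the residual sum of squares on the linear
#' survival scale.
#'
#' @slot D0 Per-target 1/e dose in Gy.
#' @slot N Extrapolation number (>= 1).
#' @slot Dq Shoulder dose `D0 * log(N)` in Gy.
#' @slot sse Residual sum of squared errors of the fit.
#' @slot data The dose-survival data used (`dose_gy`, `survival` columns).
#' @slot fitted Fitted survival probabilities at the data doses.
#'
#' @seealso [fitMultitarget()], [shoulderDose()], [survivalProbability()]
#' @export
setClass("MultitargetFit",
    slots = c(D0 = "numeric", N = "numeric", Dq = "numeric",
              sse = "numeric", data = "data.frame", fitted = "numeric")
)

setValidity("MultitargetFit", function(object) {
    msg <- character()
    if (length(object@D0) != 1L || is.na(object@D0) || object@D0 <= 0)
        msg <- c(msg, "D0 must be a positive scalar")
    if (length(object@N) != 1L || is.na(object@N) || object@N < 1)
        msg <- c(msg, "N must be a scalar >= 1")
    if (length(msg)) msg else TRUE
})
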