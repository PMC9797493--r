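#' Simulate binned coverage of mosaic seed-coat DNA
#'
#' Emulates the sequencing input of a read-depth dosage analysis:
#' seed-coat-enriched DNA modelled as a mixture of cells carrying a
#' heterozygous deletion (fraction `mutantFraction`, `m`) and non-mutated
#' contaminating cells (fraction `1 - m`). The local copy number of a bin
#' is `c = 2 - m * f` where `f` is the fraction of the bin overlapped by
#' the deletion, so the expected mean depth of the bin is
#' `meanDepth * c / 2`. Sequenced read counts per bin are Poisson
#' (optionally negative-binomial when `dispersion > 0`); the reported bin
#' statistic is the mean per-base depth, i.e. the Poisson read count scaled
#' by `readLength / width`.
#'
#' @param layout A [GenomeLayout-class]; bins tile each chromosome from
#'   position 0, the final partial bin keeping its true width.
#' @param deletion `NULL` (no deletion) or a `GRanges` of heterozygous
#'   deletion interval(s); must lie within the layout.
#' @param mutantFraction Fraction `m` in `[0, 1]` of cells carrying the
#'   deletion. Default 0.7, the level at which a heterozygous deletion in
#'   contaminated seed-coat DNA shows an RRD plateau near 0.65.
#' @param meanDepth Expected mean per-base depth at copy number 2
#'   (default 50x).
#' @param binSize Bin width in bp (default 100 kb).
#' @param readLength Read length in bp used to convert depth to Poisson
#'   read counts (default 150, paired-end 150 chemistry).
#' @param dispersion Negative-binomial overdispersion of the read counts
#'   (variance `mu + dispersion * mu^2`); 0 (default) gives pure Poisson.
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return A `GRanges` of bins with metadata column `meanDepth`.
#' @examples
#' gl <- arabidopsisLayout()
#' del <- genomicInterval("Chr4", 5600000, 7100000, gl)
#' bins <- simulateBins(gl, del, mutantFraction = 0.7, seed = 1)
#' @export
simulateBins <- function(layout, deletion = NULL, mutantFraction = 0.7,
                         meanDepth = 50, binSize = 1e5, readLength = 150,
                         dispersion = 0, seed = NULL) {
    stopifnot(is(layout, "GenomeLayout"),
              mutantFraction >= 0, mutantFraction <= 1,
              meanDepth > 0, binSize > 0, readLength > 0, dispersion >= 0)
    bins <- tileGenome(seqinfo(layout), tilewidth = binSize,
                       cut.last.tile.in.chrom = TRUE)
    frac <- numeric(length(bins))
    if (!is.null(deletion) && length(deletion) > 0) {
        sl <- chromosomeLengths(layout)
        bad <- !as.character(seqnames(deletion)) %in% names(sl)
        if (any(bad) || any(GenomicRanges::end(deletion) >
                            sl[as.character(seqnames(deletion))]))
            stop("deletion lies outside the genome layout")
        hits <- findOverlaps(bins, deletion, ignore.strand = TRUE)
        if (length(hits)) {
            ow <- GenomicRanges::width(pintersect(
                bins[queryHits(hits)], deletion[subjectHits(hits)]))
            ov <- tapply(ow, queryHits(hits), sum)
            frac[as.integer(names(ov))] <-
                ov / GenomicRanges::width(bins)[as.integer(names(ov))]
        }
    }
    cn <- 2 - mutantFraction * frac
    mu <- GenomicRanges::width(bins) * meanDepth * cn / (2 * readLength)
    draw <- function() {
        if (dispersion > 0)
            rnbinom(length(mu), mu = mu, size = 1 / dispersion)
        else
            rpois(length(mu), mu)
    }
    counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    mcols(bins)$meanDepth <- counts * readLength / GenomicRanges::width(bins)
    bins
}

#' Simulate a qPCR Ct replicate table for the TT4/TT8 copy assay
#'
#' Generates cycle-threshold values under perfect-efficiency amplification
#' (doubling per cycle): `Ct = baseCt - log2(relative copies) + noise`,
#' with the relative template copies of each target taken from the mosaic
#' copy-number model [expectedCopyNumbers()] at mutant cell fraction `m`.
#'
#' @param mutantType `"control"`, `"tt4"` or `"tt8"` — which locus lost its
#'   wild-type allele in the mutant cell lineage (control: none).
#' @param m Mutant cell fraction in `[0, 1]` (ignored for control).
#' @param baseCt Ct of one relative template copy (arbitrary level).
#' @param ctNoiseSd Gaussian technical noise on Ct, in cycles.
#' @param replicates Number of replicates per target.
#' @param sample Sample label for the output table.
#' @param model Allele copy model, see [alleleCopyModel()].
#' @param seed Integer seed or `NULL`.
#' @return data.frame with columns `sample`, `target`, `replicate`, `ct`.
#' @examples
#' simulateQpcr("tt4", m = 0.75, ctNoiseSd = 0, seed = 1)
#' @export
simulateQpcr <- function(mutantType = c("control", "tt4", "tt8"), m = 0.7,
                         baseCt = 25, ctNoiseSd = 0.15, replicates = 3,
                         sample = NULL, model = alleleCopyModel(),
                         seed = NULL) {
    mutantType <- match.arg(mutantType)
    stopifnot(replicates >= 1, ctNoiseSd >= 0, baseCt > 0)
    if (is.null(sample)) sample <- mutantType
    rel <- expectedCopyNumbers(m, mutantType, model)
    targets <- names(rel)
    out <- expand.grid(replicate = seq_len(replicates), target = targets,
                       stringsAsFactors = FALSE)
    mu <- baseCt - log2(rel[out$target])
    draw <- function() rnorm(nrow(out), mean = mu, sd = ctNoiseSd)
    ct <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    data.frame(sample = sample, target = out$target,
               replicate = out$replicate, ct = as.numeric(ct))
}

#' Simulate screening counts of a seed-color LOH screen
#'
#' Draws each plant independently into one of the classes
#' `{tt4-type, tt8-type, none}` with the given per-locus mutation
#' probabilities (a multinomial draw), emulating the screen of double
#' heterozygous M1 plants for anthocyanin-less seeds.
#'
#' @param nPlants Number of plants screened.
#' @param pLocus Named probabilities `c(tt4 = ..., tt8 = ...)`; their sum
#'   must not exceed 1.
#' @param group Label for the resulting counts.
#' @param seed Integer seed or `NULL`.
#' @return A [ScreeningCounts-class] object.
#' @examples
#' simulateScreening(2588, c(tt4 = 2/2588, tt8 = 17/2588), seed = 1)
#' @export
simulateScreening <- function(nPlants, pLocus = c(tt4 = 0, tt8 = 0),
                              group = "simulated", seed = NULL) {
    stopifnot(nPlants >= 0, all(pLocus >= 0), sum(pLocus) <= 1,
              all(c("tt4", "tt8") %in% names(pLocus)))
    p <- c(pLocus[["tt4"]], pLocus[["tt8"]])
    draw <- function() rmultinom(1, nPlants, c(p, 1 - sum(p)))
    k <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    screeningCounts(nObserved = nPlants, nTT4 = k[1L], nTT8 = k[2L],
                    group = group)
}

#' Simulate a dose-survival experiment
#'
#' Per dose, survivors are drawn as
#' `Binomial(nPerDose, S(D))` with `S` the single-hit multitarget survival
#' probability [survivalProbability()].
#'
#' @param D0 Per-target 1/e dose (Gy).
#' @param N Extrapolation number (>= 1).
#' @param doses Doses in Gy.
#' @param nPerDose Plants irradiated per dose.
#' @param seed Integer seed or `NULL`.
#' @return data.frame with columns `dose_gy`, `n_total`, `n_survived`.
#' @examples
#' simulateSurvival(D0 = 10, N = 20, doses = seq(0, 60, 10), seed = 1)
#' @export
simulateSurvival <- function(D0 = 10, N = 20, doses = seq(0, 60, 10),
                             nPerDose = 50, seed = NULL) {
    stopifnot(D0 > 0, N >= 1, all(doses >= 0), nPerDose >= 1)
    s <- survivalProbability(doses, D0, N)
    draw <- function() rbinom(length(doses), nPerDose, s)
    k <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    data.frame(dose_gy = doses, n_total = nPerDose, n_survived = k)
}
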