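#' Classify a mutant from deletion calls and a qPCR ratio
#'
#' Combines the two lines of evidence the assay produces: a deletion call
#' overlapping the TT4 locus, or a control-normalized TT4:TT8 ratio well
#' below 1, indicates loss of the wild-type TT4 allele (tt4-type); a call
#' overlapping TT8, or a ratio well above 1, indicates tt8-type. Ratios in
#' the guard band `[1/band, band]` (default 1/1.25-1.25) are treated as
#' inconclusive so noise cannot drive a call, and conflicting evidence
#' yields `"unclassified"`.
#'
#' @param calls `GRanges` of deletion calls ([callDeletions()]).
#' @param ratio Normalized TT4:TT8 ratio (scalar), e.g.
#'   `normalizedRatio(...)$ratio`.
#' @param layout A [GenomeLayout-class] whose `loci` include `TT4`, `TT8`.
#' @param band Guard band half-width factor (> 1).
#' @return `"tt4-type"`, `"tt8-type"` or `"unclassified"`.
#' @examples
#' gl <- arabidopsisLayout()
#' classifyMutant(GenomicRanges::GRanges(), 0.25, gl)  # tt4-type
#' @export
classifyMutant <- function(calls, ratio, layout, band = 1.25) {
    stopifnot(is(layout, "GenomeLayout"), band > 1, length(ratio) == 1L)
    l <- loci(layout)
    if (!all(c("TT4", "TT8") %in% names(l)))
        stop("layout must define TT4 and TT8 loci")
    ovl <- function(locus) length(calls) > 0 &&
        length(findOverlaps(l[locus], calls, ignore.strand = TRUE)) > 0
    tt4 <- ovl("TT4") || ratio < 1 / band
    tt8 <- ovl("TT8") || ratio > band
    if (tt4 && tt8) "unclassified"
    else if (tt4) "tt4-type"
    else if (tt8) "tt8-type"
    else "unclassified"
}

#' Run the full mutation-detection analysis
#'
#' Glues the pipeline end-to-end for one sequenced sample plus the cohort
#' tables: binning/normalization of the depth input, deletion calling with
#' mosaic-fraction estimates, comparative-Ct qPCR ratios for all samples
#' in the Ct table, exact binomial screening tests (equal-probability
#' two-sided and gene-length-weighted one-sided) and the seed-color
#' classification of the sequenced sample. Deterministic given its inputs.
#'
#' @param layout A [GenomeLayout-class].
#' @param depth Depth input: per-base data.frame (`chrom`, `pos`,
#'   `depth`), a `GRanges` with `meanDepth`, or a TSV path (auto-detected
#'   via [readDepthTable()]).
#' @param ct Ct table (data.frame or TSV path), may be `NULL`.
#' @param counts A [ScreeningCounts-class], TSV path, or `NULL`.
#' @param sample Name of the sequenced sample in the Ct table (defaults to
#'   the first non-control sample).
#' @param control Name of the calibrator sample in the Ct table.
#' @param binSize,threshold,minBins,gap Dosage parameters, see
#'   [binDepths()] and [callDeletions()].
#' @param geneLengths Named lengths (bp) used for the length-weighted
#'   null; defaults to the TT4/TT8 locus widths of `layout` when present,
#'   else `c(TT4 = 1789, TT8 = 4643)`.
#' @return A list (class `"mosaicReport"`) with elements `rrd` (summary),
#'   `calls`, `qpcr`, `tests`, `screening` and `classification`.
#' @export
runPipeline <- function(layout, depth, ct = NULL, counts = NULL,
                        sample = NULL, control = "control",
                        binSize = 1e5, threshold = 0.8, minBins = 3,
                        gap = 0, geneLengths = NULL) {
    stopifnot(is(layout, "GenomeLayout"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    }
    bins <- stage("dosage", {
        if (is.character(depth)) readDepthTable(depth, layout, binSize)
        else if (is.data.frame(depth)) binDepths(depth, layout, binSize)
        else depth
    })
    rrd <- stage("dosage", computeRRD(bins))
    calls <- stage("dosage",
                   callDeletions(rrd, threshold, minBins, gap))
    qpcr <- NULL
    ratio <- NA_real_
    if (!is.null(ct)) {
        qpcr <- stage("qpcr", {
            if (is.character(ct)) ct <- readCtTable(ct)
            qpcrRatios(ct, control = control)
        })
        if (is.null(sample)) sample <- qpcr$sample[1L]
        if (!sample %in% qpcr$sample)
            stop(sprintf("[qpcr] sample '%s' not in Ct table", sample))
        ratio <- qpcr$ratio[qpcr$sample == sample]
    }
    tests <- NULL
    screening <- NULL
    if (!is.null(counts)) {
        screening <- stage("screening", {
            if (is.character(counts)) {
                cl <- readScreeningCounts(counts)
                ## prefer the irradiated group if labelled, else the row
                ## with mutants
                pick <- which(vapply(cl, function(x) x@nMutant > 0,
                                     logical(1)))
                cl[[if (length(pick)) pick[1L] else 1L]]
            } else counts
        })
        if (is.null(geneLengths)) {
            l <- loci(layout)
            geneLengths <- if (all(c("TT4", "TT8") %in% names(l)))
                setNames(GenomicRanges::width(l[c("TT4", "TT8")]),
                         c("TT4", "TT8"))
            else c(TT4 = 1789, TT8 = 4643)
        }
        tests <- stage("screening", list(
            equalNull = binomTestExact(
                screening@nTT4, screening@nMutant, 0.5, "two.sided"),
            lengthWeighted = binomTestExact(
                screening@nTT4, screening@nMutant,
                lengthWeightedNull(geneLengths[["TT4"]],
                                   geneLengths[["TT8"]]), "less"),
            mutationFrequency = mutationFrequency(screening),
            classRatio = if (screening@nTT4 > 0) classRatio(screening)
                         else NA_real_))
    }
    classification <- if (!is.na(ratio))
        classifyMutant(calls, ratio, layout) else NA_character_
    structure(list(
        rrd = list(nBins = length(rrd),
                   normalizationConstant = normalizationConstant(rrd),
                   medianRRD = median(mcols(rrd)$rrd)),
        calls = calls, qpcr = qpcr, tests = tests,
        screening = screening, sample = sample,
        classification = classification),
        class = "mosaicReport")
}

#' @export
print.mosaicReport <- function(x, ...) {
    cat("== Mosaic LOH analysis report ==\n")
    cat(sprintf("RRD: %d bins, normalization %.4g, median RRD %.4g\n",
                x$rrd$nBins, x$rrd$normalizationConstant, x$rrd$medianRRD))
    cat(sprintf("Deletion calls: %d\n", length(x$calls)))
    if (length(x$calls)) {
        df <- as.data.frame(x$calls)
        for (i in seq_len(nrow(df)))
            cat(sprintf(
                "  %s:%d-%d  %.2f Mb  mean RRD %.3f  mutant fraction %.2f\n",
                df$seqnames[i], df$start[i] - 1L, df$end[i],
                df$sizeBp[i] / 1e6, df$meanRRD[i], df$mutantFraction[i]))
    }
    if (!is.null(x$qpcr)) {
        cat("qPCR normalized TT4:TT8 ratios:\n")
        for (i in seq_len(nrow(x$qpcr)))
            cat(sprintf("  %s: %.3f (SE %.3f)\n", x$qpcr$sample[i],
                        x$qpcr$ratio[i], x$qpcr$se[i]))
    }
    if (!is.null(x$tests)) {
        cat(sprintf("Screening: %d/%d mutant (%.1f%%)\n",
                    x$screening@nMutant, x$screening@nObserved,
                    x$tests$mutationFrequency))
        cat(sprintf("  equal-null two-sided p = %.3g\n",
                    x$tests$equalNull$p.value))
        cat(sprintf("  length-weighted one-sided p = %.3g\n",
                    x$tests$lengthWeighted$p.value))
    }
    if (!is.na(x$classification))
        cat(sprintf("Classification of '%s': %s\n",
                    x$sample, x$classification))
    invisible(x)
}
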