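#' Bin per-base depths into fixed-width genomic bins
#'
#' Tiles each chromosome of the layout from position 0 with
#' `binSize`-wide non-overlapping bins (the final partial bin keeps its
#' true width) and computes the mean per-base depth of each bin. Positions
#' absent from the input count as depth 0, so the mean is always taken
#' over the full bin width.
#'
#' @param perBase data.frame with columns `chrom`, `pos` (1-based) and
#'   `depth`, e.g. the output of a per-base depth tool.
#' @param layout A [GenomeLayout-class].
#' @param binSize Bin width in bp (default 100 kb).
#' @return `GRanges` of bins with metadata column `meanDepth`.
#' @examples
#' gl <- genomeLayout(c(chrA = 250000))
#' pb <- data.frame(chrom = "chrA", pos = 1:50000, depth = 10)
#' binDepths(pb, gl)
#' @export
binDepths <- function(perBase, layout, binSize = 1e5) {
    stopifnot(is(layout, "GenomeLayout"), binSize > 0)
    need <- c("chrom", "pos", "depth")
    if (!all(need %in% names(perBase)))
        stop("perBase needs columns: ", paste(need, collapse = ", "))
    sl <- chromosomeLengths(layout)
    bad <- !perBase$chrom %in% names(sl)
    if (any(bad))
        stop(sprintf("unknown chromosome '%s' in depth input (row %d)",
                     perBase$chrom[which(bad)[1L]], which(bad)[1L]))
    out <- perBase$pos < 1 | perBase$pos > sl[perBase$chrom]
    if (any(out))
        stop(sprintf("position outside chromosome in depth input (row %d)",
                     which(out)[1L]))
    bins <- tileGenome(seqinfo(layout), tilewidth = binSize,
                       cut.last.tile.in.chrom = TRUE)
    total <- numeric(length(bins))
    if (nrow(perBase) > 0) {
        pos <- GRanges(perBase$chrom, IRanges(perBase$pos, width = 1L),
                       seqinfo = seqinfo(layout))
        hits <- findOverlaps(pos, bins)
        s <- tapply(perBase$depth[queryHits(hits)], subjectHits(hits), sum)
        total[as.integer(names(s))] <- s
    }
    mcols(bins)$meanDepth <- total / GenomicRanges::width(bins)
    bins
}

#' Compute relative read depth (RRD)
#'
#' Divides each bin's mean depth by the median mean depth over *all* bins
#' of all chromosomes in the table. In a non-deleted diploid region the
#' RRD is therefore ~1; a heterozygous deletion carried by a fraction `m`
#' of cells depresses it to `1 - m/2` (0.65 at `m = 0.7`, 0.5 in a pure
#' hemizygote).
#'
#' @param bins `GRanges` with metadata column `meanDepth`, e.g. from
#'   [binDepths()] or [simulateBins()].
#' @return An [RRDTable-class]; the median used is available as
#'   `normalizationConstant(x)`.
#' @examples
#' gl <- genomeLayout(c(chrA = 300000))
#' b <- GenomicRanges::GRanges(c("chrA", "chrA", "chrA"),
#'     IRanges::IRanges(c(1, 100001, 200001), c(100000, 200000, 300000)),
#'     meanDepth = c(10, 10, 5))
#' computeRRD(b)
#' @export
computeRRD <- function(bins) {
    if (!"meanDepth" %in% colnames(mcols(bins)))
        stop("bins need a 'meanDepth' metadata column")
    d <- mcols(bins)$meanDepth
    k <- median(d)
    if (!any(d > 0) || k <= 0)
        stop("cannot normalize: median bin depth is zero")
    bins <- GenomicRanges::sort(bins, ignore.strand = TRUE)
    mcols(bins)$rrd <- mcols(bins)$meanDepth / k
    metadata(bins)$normalizationConstant <- k
    new("RRDTable", bins)
}

#' @rdname RRDTable-class
#' @export
setMethod("normalizationConstant", "RRDTable",
    function(x) metadata(x)$normalizationConstant)

setMethod("show", "RRDTable", function(object) {
    cat("RRDTable:", length(object), "bins on",
        length(unique(as.character(seqnames(object)))), "chromosomes;",
        "normalization constant", signif(normalizationConstant(object), 5),
        "\n")
    cat("  median RRD", signif(median(mcols(object)$rrd), 5),
        "| range", paste(signif(range(mcols(object)$rrd), 3),
                         collapse = " - "), "\n")
})

#' Call mosaic deletions as runs of depressed RRD bins
#'
#' Scans each chromosome for maximal runs of consecutive bins with
#' `rrd < threshold` of length at least `minBins` and reports each run as
#' a deletion call with its bin-aligned interval, size, mean RRD and the
#' mutant cell fraction estimate `clamp(2 * (1 - meanRRD), 0, 1)`.
#' Runs are by default not merged across an above-threshold bin; set
#' `gap > 0` to bridge up to that many interrupting bins.
#'
#' The defaults (threshold 0.8, minBins 3) separate the RRD ~0.65 plateau
#' of a deletion carried by ~70% of cells from the RRD ~1 background at
#' coverage of ~30x and above, while requiring 300 kb of support at the
#' default 100-kb bin size.
#'
#' @param rrd An [RRDTable-class].
#' @param threshold RRD below which a bin is "depressed", in `(0, 1]`.
#' @param minBins Minimum run length (bins) reported.
#' @param gap Merge runs separated by at most this many above-threshold
#'   bins (default 0: no merging).
#' @return `GRanges` of calls (sorted, non-overlapping) with metadata
#'   columns `nBins`, `sizeBp`, `meanRRD`, `mutantFraction`.
#' @examples
#' gl <- arabidopsisLayout()
#' del <- genomicInterval("Chr4", 5000000, 6900000, gl)
#' x <- computeRRD(simulateBins(gl, del, seed = 1))
#' callDeletions(x)
#' @export
callDeletions <- function(rrd, threshold = 0.8, minBins = 3, gap = 0) {
    stopifnot(is(rrd, "RRDTable"))
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    stopifnot(minBins >= 1, gap >= 0)
    calls <- list()
    for (chr in unique(as.character(seqnames(rrd)))) {
        x <- rrd[as.character(seqnames(rrd)) == chr]
        below <- mcols(x)$rrd < threshold
        if (gap > 0 && any(below)) {
            r <- rle(below)
            n <- length(r$values)
            bridge <- !r$values & r$lengths <= gap &
                seq_len(n) > 1L & seq_len(n) < n
            r$values[bridge] <- TRUE
            below <- inverse.rle(r)
        }
        r <- rle(below)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        keep <- r$values & r$lengths >= minBins
        for (i in which(keep)) {
            run <- x[starts[i]:ends[i]]
            calls[[length(calls) + 1L]] <- GRanges(
                chr,
                IRanges(min(GenomicRanges::start(run)),
                        max(GenomicRanges::end(run))),
                seqinfo = seqinfo(rrd),
                nBins = length(run),
                sizeBp = sum(GenomicRanges::width(run)),
                meanRRD = mean(mcols(run)$rrd),
                mutantFraction = estimateMutantFraction(
                    mean(mcols(run)$rrd)))
        }
    }
    if (!length(calls))
        return(GRanges(seqinfo = seqinfo(rrd),
                       nBins = integer(), sizeBp = integer(),
                       meanRRD = numeric(), mutantFraction = numeric()))
    GenomicRanges::sort(do.call(c, calls), ignore.strand = TRUE)
}

#' Mean RRD over the bins overlapping a locus
#'
#' Depth-unweighted mean of `rrd` over all bins overlapping the locus by
#' at least 1 bp — the per-locus summary plotted in a dosage analysis.
#'
#' @param rrd An [RRDTable-class].
#' @param locus Length-1 `GRanges`.
#' @return Mean RRD (scalar).
#' @examples
#' gl <- arabidopsisLayout()
#' x <- computeRRD(simulateBins(gl, seed = 1))
#' locusRRD(x, loci(gl)["TT8"])
#' @export
locusRRD <- function(rrd, locus) {
    stopifnot(is(rrd, "RRDTable"), length(locus) == 1L)
    if (!as.character(seqnames(locus)) %in%
            unique(as.character(seqnames(rrd))))
        stop("locus overlaps no bin of the RRD table")
    hits <- findOverlaps(locus, granges(rrd), ignore.strand = TRUE)
    if (!length(hits))
        stop("locus overlaps no bin of the RRD table")
    mean(mcols(rrd)$rrd[subjectHits(hits)])
}

#' Estimate the mutant cell fraction from a mean RRD
#'
#' Inverts the mixture copy-number model: over a heterozygous deletion
#' carried by a fraction `m` of cells the local copy number is `2 - m`, so
#' the normalized depth is `(2 - m)/2` and `m = 2 * (1 - RRD)`, clamped to
#' `[0, 1]`.
#'
#' @param meanRRD Mean RRD over the deleted region (non-negative; may be a
#'   vector).
#' @return Estimated mutant cell fraction(s) in `[0, 1]`.
#' @examples
#' estimateMutantFraction(c(1, 0.65, 0.5))  # 0, 0.7, 1
#' @export
estimateMutantFraction <- function(meanRRD) {
    if (any(meanRRD < 0))
        stop("meanRRD must be non-negative")
    pmin(pmax(2 * (1 - meanRRD), 0), 1)
}

#' Plot RRD along chromosomes
#'
#' Basic per-chromosome scatter of RRD versus position (one panel per
#' chromosome), with the theoretical diploid level 1 and an optional call
#' threshold marked, and locus positions from a layout highlighted.
#'
#' @param rrd An [RRDTable-class].
#' @param chroms Chromosomes to plot (default: all in the table).
#' @param threshold Optional horizontal threshold line.
#' @param layout Optional [GenomeLayout-class] whose loci are marked.
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plotRRD <- function(rrd, chroms = NULL, threshold = 0.8, layout = NULL) {
    stopifnot(is(rrd, "RRDTable"))
    if (is.null(chroms))
        chroms <- unique(as.character(seqnames(rrd)))
    old <- graphics::par(mfrow = c(length(chroms), 1),
                         mar = c(3.5, 4, 1.5, 1))
    on.exit(graphics::par(old))
    for (chr in chroms) {
        x <- rrd[as.character(seqnames(rrd)) == chr]
        mid <- (GenomicRanges::start(x) + GenomicRanges::end(x)) / 2e6
        plot(mid, mcols(x)$rrd, pch = 16, cex = 0.5, ylim = c(0, 1.6),
             xlab = "", ylab = "RRD", main = chr)
        graphics::mtext("position (Mb)", side = 1, line = 2, cex = 0.7)
        graphics::abline(h = 1, col = "grey50", lty = 2)
        if (!is.null(threshold))
            graphics::abline(h = threshold, col = "firebrick", lty = 3)
        if (!is.null(layout)) {
            l <- loci(layout)
            l <- l[as.character(seqnames(l)) == chr]
            if (length(l))
                graphics::abline(v = GenomicRanges::start(l) / 1e6,
                                 col = "orange")
        }
    }
    invisible(NULL)
}
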