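## Small layouts and builders shared across test files.

toyLayout <- function() {
    genomeLayout(
        c(chrA = 2e6, chrB = 1e6),
        loci = data.frame(name = c("TT4", "TT8"),
                          chrom = c("chrB", "chrA"),
                          start = c(4e5, 1e6),
                          end = c(4e5 + 1789, 1e6 + 4643)))
}

## GRanges of contiguous bins on one chromosome with given mean depths
makeBins <- function(depths, binSize = 1e5, chrom = "chrA",
                     chromLen = length(depths) * binSize) {
    starts <- seq(0, by = binSize, length.out = length(depths))
    GenomicRanges::GRanges(
        chrom,
        IRanges::IRanges(starts + 1, pmin(starts + binSize, chromLen)),
        meanDepth = depths)
}

rrdFromDepths <- function(depths, ...) computeRRD(makeBins(depths, ...))

## RRDTable with prescribed rrd values (bypasses the median so fixtures
## can state the rrd directly)
rrdTableFromRRD <- function(rrd, binSize = 1e5, chrom = "chrA", norm = 50) {
    gr <- makeBins(rrd * norm, binSize = binSize, chrom = chrom)
    S4Vectors::mcols(gr)$rrd <- rrd
    S4Vectors::metadata(gr)$normalizationConstant <- norm
    new("RRDTable", gr)
}

## exhaustive enumeration of maximal below-threshold runs (oracle for
## callDeletions on a single chromosome, no gap merging)
bruteForceRuns <- function(rrd, threshold, minBins) {
    below <- rrd < threshold
    runs <- list()
    i <- 1L
    while (i <= length(below)) {
        if (below[i]) {
            j <- i
            while (j < length(below) && below[j + 1L]) j <- j + 1L
            if (j - i + 1L >= minBins)
                runs[[length(runs) + 1L]] <- c(start = i, end = j)
            i <- j + 1L
        } else i <- i + 1L
    }
    runs
}
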