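#' Construct a GenomeLayout
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a data.frame with columns
#'   `name`, `length`.
#' @param loci,ampliconTargets Named [GenomicRanges::GRanges], or a
#'   data.frame with columns `name`, `chrom`, `start`, `end` in 0-based
#'   half-open coordinates (the on-disk convention).
#' @return A [GenomeLayout-class] object.
#' @examples
#' gl <- genomeLayout(
#'     c(chrA = 2e6, chrB = 1e6),
#'     loci = data.frame(name = "G1", chrom = "chrA", start = 5e5, end = 6e5))
#' chromosomeLengths(gl)
#' @export
genomeLayout <- function(chromosomes, loci = GRanges(),
                         ampliconTargets = GRanges()) {
    if (is.data.frame(chromosomes))
        chromosomes <- setNames(chromosomes$length, chromosomes$name)
    si <- Seqinfo(seqnames = names(chromosomes),
                  seqlengths = as.integer(chromosomes))
    new("GenomeLayout", seqinfo = si,
        loci = .asLayoutGRanges(loci, si, "loci"),
        ampliconTargets = .asLayoutGRanges(ampliconTargets, si,
                                           "amplicon targets"))
}

## data.frame (0-based half-open) or GRanges -> GRanges on the layout Seqinfo
.asLayoutGRanges <- function(x, si, what) {
    if (is.data.frame(x)) {
        if (nrow(x) == 0L) return(GRanges(seqinfo = si))
        bad <- !x$chrom %in% seqlevels(si)
        if (any(bad))
            stop(sprintf("%s on unknown chromosome: %s", what,
                         paste(x$name[bad], collapse = ", ")))
        out <- x$start < 0 | x$end > seqlengths(si)[x$chrom]
        if (any(out))
            stop(sprintf("%s outside chromosome bounds: %s", what,
                         paste(x$name[out], collapse = ", ")))
        x <- GRanges(x$chrom, IRanges(x$start + 1L, x$end),
                     seqinfo = si, name = x$name)
        names(x) <- mcols(x)$name
        mcols(x)$name <- NULL
    } else {
        bad <- !as.character(seqnames(x)) %in% seqlevels(si)
        if (any(bad))
            stop(sprintf("%s on unknown chromosome: %s", what,
                         paste(names(x)[bad], collapse = ", ")))
        x <- GRanges(as.character(seqnames(x)),
                     IRanges(GenomicRanges::start(x), GenomicRanges::end(x)),
                     seqinfo = si)
        names(x) <- names(x)
    }
    x
}

#' @rdname GenomeLayout-class
#' @export
setMethod("chromosomeLengths", "GenomeLayout",
    function(x) seqlengths(x@seqinfo))

#' @rdname GenomeLayout-class
#' @export
setMethod("loci", "GenomeLayout", function(x) x@loci)

#' @rdname GenomeLayout-class
#' @export
setMethod("ampliconTargets", "GenomeLayout", function(x) x@ampliconTargets)

#' @rdname GenomeLayout-class
#' @export
setMethod("seqinfo", "GenomeLayout", function(x) x@seqinfo)

setMethod("show", "GenomeLayout", function(object) {
    sl <- seqlengths(object@seqinfo)
    cat("GenomeLayout with", length(sl), "chromosomes (",
        round(sum(as.numeric(sl)) / 1e6, 1), "Mb )\n")
    cat("  loci:", if (length(object@loci))
        paste(names(object@loci), collapse = ", ") else "none", "\n")
    cat("  amplicon targets:", length(object@ampliconTargets), "\n")
})

#' Default five-chromosome Arabidopsis layout
#'
#' Ships the five nuclear Arabidopsis thaliana chromosomes at their
#' reference (TAIR10) lengths, with *approximate* positions for the two
#' seed-color marker loci: `TT4` (chalcone synthase, 1789 bp including
#' UTRs, chromosome 5) and `TT8` (seed-coat transcription factor, 4643 bp
#' including UTRs, chromosome 4), plus one qPCR target inside each locus.
#' Organelle sequences are excluded: the RRD normalization median is taken
#' over the five nuclear chromosomes only. Locus coordinates are
#' configurable — pass your own layout wherever one is accepted.
#'
#' @return A [GenomeLayout-class].
#' @examples
#' arabidopsisLayout()
#' @export
arabidopsisLayout <- function() {
    genomeLayout(
        c(Chr1 = 30427671, Chr2 = 19698289, Chr3 = 23459830,
          Chr4 = 18585056, Chr5 = 26975502),
        loci = data.frame(
            name = c("TT8", "TT4"),
            chrom = c("Chr4", "Chr5"),
            start = c(6200000, 4480000),
            end = c(6204643, 4481789)),
        ampliconTargets = data.frame(
            name = c("TT8_q", "TT4_q"),
            chrom = c("Chr4", "Chr5"),
            start = c(6202000, 4480500),
            end = c(6202120, 4480620)))
}

#' Build a genomic interval from 0-based half-open coordinates
#'
#' Convenience constructor converting the on-disk convention (0-based
#' start inclusive, end exclusive) to the 1-based closed
#' [GenomicRanges::GRanges] used in memory.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param layout Optional [GenomeLayout-class]; when given, the interval is
#'   checked against its chromosomes and carries its Seqinfo.
#' @return A length-1 `GRanges`.
#' @examples
#' genomicInterval("Chr4", 5600000, 7100000, arabidopsisLayout())
#' @export
genomicInterval <- function(chrom, start, end, layout = NULL) {
    stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
    if (start < 0 || end <= start)
        stop("need 0 <= start < end (0-based half-open)")
    if (is.null(layout))
        return(GRanges(chrom, IRanges(start + 1, end)))
    sl <- chromosomeLengths(layout)
    if (!chrom %in% names(sl))
        stop(sprintf("unknown chromosome '%s'", chrom))
    if (end > sl[[chrom]])
        stop(sprintf("interval end %d exceeds length of %s (%d)",
                     end, chrom, sl[[chrom]]))
    GRanges(chrom, IRanges(start + 1, end), seqinfo = seqinfo(layout))
}

#' Overlap length of two genomic intervals
#'
#' @param a,b Length-1 [GenomicRanges::GRanges].
#' @return Overlap in bp; 0 if the intervals are on different chromosomes
#'   or disjoint. Symmetric, and never exceeds the shorter interval.
#' @examples
#' a <- genomicInterval("chr4", 0, 100)
#' b <- genomicInterval("chr4", 50, 150)
#' intervalOverlap(a, b)  # 50
#' @export
intervalOverlap <- function(a, b) {
    stopifnot(length(a) == 1L, length(b) == 1L)
    if (as.character(seqnames(a)) != as.character(seqnames(b)))
        return(0L)
    w <- min(GenomicRanges::end(a), GenomicRanges::end(b)) -
         max(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
    max(0L, w)
}

#' Predict which PCR amplicons survive a deletion
#'
#' A primer pair fails as soon as any of its template is deleted: a target
#' is called `"absent"` iff it overlaps the deletion by at least 1 bp,
#' `"present"` otherwise. This reproduces the banding pattern of
#' site-specific PCR across a large deletion, where the fragments inside
#' the deleted region drop out and the flanking ones amplify.
#'
#' @param deletion Length-1 `GRanges` (the deleted interval).
#' @param targets Named `GRanges` of amplicon targets, or a
#'   [GenomeLayout-class] (its `ampliconTargets` are used).
#' @param layout Optional [GenomeLayout-class] against whose chromosomes
#'   the targets are validated; a target on an unknown chromosome is an
#'   error naming that target.
#' @return Named character vector, `"present"` or `"absent"` per target.
#' @examples
#' gl <- arabidopsisLayout()
#' del <- genomicInterval("Chr4", 5600000, 7100000, gl)
#' predictAmplicons(del, gl)
#' @export
predictAmplicons <- function(deletion, targets, layout = NULL) {
    stopifnot(length(deletion) == 1L)
    if (is(targets, "GenomeLayout")) {
        if (is.null(layout)) layout <- targets
        targets <- ampliconTargets(targets)
    }
    if (!is.null(layout)) {
        known <- names(chromosomeLengths(layout))
        bad <- !as.character(seqnames(targets)) %in% known
        if (any(bad))
            stop(sprintf("target(s) on unknown chromosome: %s",
                         paste(names(targets)[bad], collapse = ", ")))
    }
    hit <- vapply(seq_along(targets), function(i)
        intervalOverlap(targets[i], deletion) > 0, logical(1))
    setNames(ifelse(hit, "absent", "present"), names(targets))
}
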