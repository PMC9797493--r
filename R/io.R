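## TSV readers/writers. All on-disk interval coordinates are 0-based
## half-open (BED convention); conversion to 1-based GRanges happens here.

.readTsv <- function(path, required, numericCols = character()) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path))
    df <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE, check.names = FALSE,
                     colClasses = "character")
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop(sprintf("%s: missing column(s): %s", path,
                     paste(missing, collapse = ", ")))
    for (col in numericCols) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA"
        if (any(bad))
            stop(sprintf("%s: line %d: non-numeric value '%s' in column '%s'",
                         path, which(bad)[1L] + 1L,  # +1 for the header line
                         df[[col]][which(bad)[1L]], col))
        df[[col]] <- v
    }
    df
}

.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read a genome layout from a YAML config
#'
#' The config has a `chromosomes` list (`name`, `length`) and optional
#' `loci` and `amplicon_targets` lists (`name`, `chrom`, `start`, `end`;
#' 0-based half-open).
#'
#' @param path Path to the YAML file.
#' @return A [GenomeLayout-class].
#' @examples
#' cfg <- system.file("extdata", "arabidopsis_layout.yaml",
#'                    package = "MosaicLOH")
#' readGenomeLayout(cfg)
#' @export
readGenomeLayout <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$chromosomes))
        stop(sprintf("%s: no 'chromosomes' section", path))
    chroms <- vapply(cfg$chromosomes, function(x) as.numeric(x$length),
                     numeric(1))
    names(chroms) <- vapply(cfg$chromosomes, function(x)
        as.character(x$name), character(1))
    asDf <- function(entries) {
        if (is.null(entries)) return(GRanges())
        do.call(rbind, lapply(entries, function(x)
            data.frame(name = as.character(x$name),
                       chrom = as.character(x$chrom),
                       start = as.numeric(x$start),
                       end = as.numeric(x$end))))
    }
    genomeLayout(chroms, loci = asDf(cfg$loci),
                 ampliconTargets = asDf(cfg$amplicon_targets))
}

#' Read depth input, auto-detecting per-base vs binned format
#'
#' A 3-column table (`chrom`, `pos`, `depth`; 1-based positions) is
#' treated as per-base depth; a 4-column table (`chrom`, `start`, `end`,
#' `mean_depth`; 0-based half-open) as pre-binned depth.
#'
#' @param path TSV path.
#' @param layout A [GenomeLayout-class] (used for validation / Seqinfo).
#' @param binSize Bin width applied when the input is per-base.
#' @return `GRanges` of bins with metadata column `meanDepth`.
#' @export
readDepthTable <- function(path, layout, binSize = 1e5) {
    header <- names(read.delim(path, sep = "\t", nrows = 1,
                               check.names = FALSE))
    if (length(header) == 3L) {
        df <- .readTsv(path, c("chrom", "pos", "depth"), c("pos", "depth"))
        binDepths(df, layout, binSize)
    } else {
        readBinDepths(path, layout)
    }
}

#' @rdname readDepthTable
#' @export
readBinDepths <- function(path, layout) {
    df <- .readTsv(path, c("chrom", "start", "end", "mean_depth"),
                   c("start", "end", "mean_depth"))
    bad <- !df$chrom %in% names(chromosomeLengths(layout))
    if (any(bad))
        stop(sprintf("%s: line %d: unknown chromosome '%s'",
                     path, which(bad)[1L] + 1L, df$chrom[which(bad)[1L]]))
    GRanges(df$chrom, IRanges(df$start + 1, df$end),
            seqinfo = seqinfo(layout), meanDepth = df$mean_depth)
}

#' Write / read an RRD table as TSV
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `mean_depth`,
#' `rrd`, `normalization_constant` (repeated on every row so the file is
#' self-contained). `readRRDTable` reconstructs the identical
#' [RRDTable-class].
#'
#' @param rrd An [RRDTable-class].
#' @param path TSV path.
#' @param layout A [GenomeLayout-class].
#' @return `writeRRDTable` the path, invisibly; `readRRDTable` the table.
#' @export
writeRRDTable <- function(rrd, path) {
    stopifnot(is(rrd, "RRDTable"))
    .writeTsv(data.frame(
        chrom = as.character(seqnames(rrd)),
        start = GenomicRanges::start(rrd) - 1L,
        end = GenomicRanges::end(rrd),
        mean_depth = mcols(rrd)$meanDepth,
        rrd = mcols(rrd)$rrd,
        normalization_constant = normalizationConstant(rrd)), path)
}

#' @rdname writeRRDTable
#' @export
readRRDTable <- function(path, layout) {
    df <- .readTsv(path,
        c("chrom", "start", "end", "mean_depth", "rrd",
          "normalization_constant"),
        c("start", "end", "mean_depth", "rrd", "normalization_constant"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end),
                  seqinfo = seqinfo(layout),
                  meanDepth = df$mean_depth, rrd = df$rrd)
    metadata(gr)$normalizationConstant <- df$normalization_constant[1L]
    new("RRDTable", gr)
}

#' Write deletion calls as a BED-like TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `name`,
#' `mean_rrd`, `mutant_fraction_est`.
#'
#' @param calls `GRanges` from [callDeletions()].
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
writeDeletionCalls <- function(calls, path) {
    nm <- if (length(calls))
        sprintf("del_%d", seq_along(calls)) else character()
    .writeTsv(data.frame(
        chrom = as.character(seqnames(calls)),
        start = GenomicRanges::start(calls) - 1L,
        end = GenomicRanges::end(calls),
        name = nm,
        mean_rrd = mcols(calls)$meanRRD,
        mutant_fraction_est = mcols(calls)$mutantFraction), path)
}

#' Read / write a qPCR Ct table
#'
#' Columns `sample`, `target`, `replicate`, `ct`.
#'
#' @param ct data.frame of Ct replicates.
#' @param path TSV path.
#' @return `readCtTable` the data.frame; `writeCtTable` the path.
#' @export
readCtTable <- function(path) {
    df <- .readTsv(path, c("sample", "target", "replicate", "ct"),
                   c("replicate", "ct"))
    bad <- !df$target %in% c("TT4", "TT8")
    if (any(bad))
        stop(sprintf("%s: line %d: unknown target '%s'",
                     path, which(bad)[1L] + 1L, df$target[which(bad)[1L]]))
    df
}

#' @rdname readCtTable
#' @export
writeCtTable <- function(ct, path) .writeTsv(ct, path)

#' Read screening counts from a TSV shaped like a screening table
#'
#' Columns `group`, `n_observed`, `n_tt4`, `n_tt8` (one row per
#' population).
#'
#' @param path TSV path.
#' @return List of [ScreeningCounts-class], named by group.
#' @export
readScreeningCounts <- function(path) {
    df <- .readTsv(path, c("group", "n_observed", "n_tt4", "n_tt8"),
                   c("n_observed", "n_tt4", "n_tt8"))
    out <- lapply(seq_len(nrow(df)), function(i)
        screeningCounts(df$n_observed[i], df$n_tt4[i], df$n_tt8[i],
                        group = df$group[i]))
    names(out) <- df$group
    out
}

#' Read a dose-survival table
#'
#' Columns `dose_gy`, `n_total`, `n_survived`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSurvivalData <- function(path) {
    .readTsv(path, c("dose_gy", "n_total", "n_survived"),
             c("dose_gy", "n_total", "n_survived"))
}
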