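#' Allele copy model for the two-locus qPCR assay
#'
#' Describes, per qPCR target, how many template copies sit on the
#' wild-type and on the mutant allele of the *control* double
#' heterozygote. In the reference assay the TT4 target lies inside the
#' region deleted from the mutant (tt4) allele, so the control carries it
#' on the wild-type allele only — `(wildtype = 1, mutant = 0)`; the tt8
#' lesion is a single-nucleotide deletion, so the TT8 target is present on
#' both alleles — `(1, 1)`.
#'
#' @param TT4,TT8 Length-2 vectors `c(wildtype, mutant)` with entries in
#'   `{0, 1}`.
#' @return A named list (the model) used by [expectedCopyNumbers()].
#' @export
alleleCopyModel <- function(TT4 = c(wildtype = 1, mutant = 0),
                            TT8 = c(wildtype = 1, mutant = 1)) {
    model <- list(TT4 = TT4, TT8 = TT8)
    for (t in names(model)) {
        if (length(model[[t]]) != 2L || !all(model[[t]] %in% c(0, 1)))
            stop(sprintf("copies for %s must be two values in {0, 1}", t))
    }
    model
}

#' Expected relative template copies in a mosaic sample
#'
#' Forward model for the comparative-Ct assay on seed-coat-enriched DNA: a
#' fraction `m` of cells carries a de novo deletion of the *wild-type*
#' allele at the mutated locus (losing that allele's target copies), while
#' the remaining `1 - m` contaminating cells keep the control genotype.
#' Per-target copies per cell are averaged over the mixture and returned
#' relative to the control copies.
#'
#' @param m Mutant cell fraction in `[0, 1]`.
#' @param mutantType `"control"`, `"tt4"` or `"tt8"`.
#' @param model An [alleleCopyModel()].
#' @return Named numeric `c(TT4 = ..., TT8 = ...)` of relative copies.
#' @examples
#' expectedCopyNumbers(0.75, "tt4")  # TT4 0.25, TT8 1
#' expectedCopyNumbers(0.7, "tt8")   # TT4 1,    TT8 0.65
#' @export
expectedCopyNumbers <- function(m, mutantType = c("control", "tt4", "tt8"),
                                model = alleleCopyModel()) {
    mutantType <- match.arg(mutantType)
    stopifnot(m >= 0, m <= 1)
    ctrl <- vapply(model, sum, numeric(1))
    mut <- ctrl
    if (mutantType != "control") {
        locus <- toupper(mutantType)            # "tt4" -> "TT4"
        mut[locus] <- ctrl[locus] - model[[locus]][["wildtype"]]
    }
    mixed <- (1 - m) * ctrl + m * mut
    mixed / ctrl
}

#' Expected control-normalized TT4:TT8 ratio of a mosaic sample
#'
#' Ratio of the relative TT4 copies to the relative TT8 copies from
#' [expectedCopyNumbers()] — what a noiseless comparative-Ct measurement
#' of the mosaic sample, normalized to the control, would report. It is 1
#' at `m = 0`, decreases with `m` for a tt4-type mosaic (0.25 at
#' `m = 0.75`) and increases for a tt8-type mosaic (2/1.3 ~ 1.54 at
#' `m = 0.7`).
#'
#' @inheritParams expectedCopyNumbers
#' @return The expected normalized ratio (scalar).
#' @examples
#' expectedRatio(0.75, "tt4")  # 0.25
#' expectedRatio(0.7, "tt8")   # ~1.54
#' @export
expectedRatio <- function(m, mutantType = c("control", "tt4", "tt8"),
                          model = alleleCopyModel()) {
    rel <- expectedCopyNumbers(m, mutantType, model)
    unname(rel[["TT4"]] / rel[["TT8"]])
}

.meanCt <- function(ct, sample, target) {
    rows <- ct$target == target
    if (!any(rows))
        stop(sprintf("sample '%s' has no Ct values for target '%s'",
                     sample, target))
    mean(ct$ct[rows])
}

.deltaCt <- function(ct, sample) {
    .meanCt(ct, sample, "TT4") - .meanCt(ct, sample, "TT8")
}

#' Control-normalized TT4:TT8 copy ratio by the comparative Ct method
#'
#' Computes `dCt = mean(Ct_TT4) - mean(Ct_TT8)` for the sample and the
#' control, and returns `ratio = 2^-(dCt_sample - dCt_control)` — the
#' TT4:TT8 template ratio normalized against the control, assuming perfect
#' doubling per cycle.
#'
#' @param sampleCt,controlCt data.frames of Ct replicates with columns
#'   `target` (`"TT4"`/`"TT8"`) and `ct`; an optional `sample` column
#'   labels the output.
#' @return List with `sample`, `ratio` and `controlDeltaCt` (cycles).
#' @examples
#' s <- simulateQpcr("tt4", m = 0.75, ctNoiseSd = 0, seed = 1)
#' ctl <- simulateQpcr("control", ctNoiseSd = 0, seed = 2)
#' normalizedRatio(s, ctl)$ratio  # 0.25
#' @export
normalizedRatio <- function(sampleCt, controlCt) {
    sname <- if ("sample" %in% names(sampleCt) && nrow(sampleCt))
        sampleCt$sample[1L] else "sample"
    cname <- if ("sample" %in% names(controlCt) && nrow(controlCt))
        controlCt$sample[1L] else "control"
    dS <- .deltaCt(sampleCt, sname)
    dC <- .deltaCt(controlCt, cname)
    list(sample = sname, ratio = 2^-(dS - dC), controlDeltaCt = dC)
}

#' Per-sample normalized qPCR ratios with replicate standard errors
#'
#' Applies [normalizedRatio()] to every non-control sample of a Ct table.
#' The point estimate uses the mean Ct per target; the standard error is
#' taken over replicate-wise ratios (replicate i's dCt against the
#' control's mean dCt), matching the convention of reporting the mean and
#' SE of biological replicates.
#'
#' @param ct data.frame with columns `sample`, `target`, `replicate`, `ct`.
#' @param control Name of the control (calibrator) sample.
#' @return data.frame with one row per sample: `sample`, `ratio`, `se`,
#'   `nReplicates`, `controlDeltaCt`.
#' @export
qpcrRatios <- function(ct, control = "control") {
    need <- c("sample", "target", "replicate", "ct")
    if (!all(need %in% names(ct)))
        stop("Ct table needs columns: ", paste(need, collapse = ", "))
    if (!control %in% ct$sample)
        stop(sprintf("control sample '%s' not found in Ct table", control))
    ctlRows <- ct[ct$sample == control, ]
    dC <- .deltaCt(ctlRows, control)
    samples <- setdiff(unique(ct$sample), control)
    res <- lapply(samples, function(s) {
        rows <- ct[ct$sample == s, ]
        nr <- normalizedRatio(rows, ctlRows)
        t4 <- rows[rows$target == "TT4", ]
        t8 <- rows[rows$target == "TT8", ]
        se <- NA_real_
        n <- min(nrow(t4), nrow(t8))
        if (nrow(t4) == nrow(t8) && n > 1) {
            t4 <- t4[order(t4$replicate), ]
            t8 <- t8[order(t8$replicate), ]
            rep_ratio <- 2^-((t4$ct - t8$ct) - dC)
            se <- sd(rep_ratio) / sqrt(n)
        }
        data.frame(sample = s, ratio = nr$ratio, se = se,
                   nReplicates = n, controlDeltaCt = dC)
    })
    do.call(rbind, res)
}
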