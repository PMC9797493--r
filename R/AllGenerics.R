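#' @rdname GenomeLayout-class
#' @param x,object A `GenomeLayout`.
#' @export
setGeneric("chromosomeLengths", function(x) standardGeneric("chromosomeLengths"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenomeLayout-class
#' @export
setGeneric("ampliconTargets", function(x) standardGeneric("ampliconTargets"))

#' @rdname RRDTable-class
#' @param x An `RRDTable`.
#' @export
setGeneric("normalizationConstant",
    function(x) standardGeneric("normalizationConstant"))

#' Shoulder (quasi-threshold) dose of a multitarget survival curve
#'
#' The quasi-threshold dose `Dq = D0 * log(N)` marks the end of the
#' low-dose survival plateau of the single-hit multitarget model — the
#' quantitative counterpart of the dose at which survival starts to drop
#' sharply from ~100%.
#'
#' @param object A [MultitargetFit-class] object, or a numeric `D0` (Gy).
#' @param N Extrapolation number, required when `object` is numeric.
#' @return Shoulder dose in Gy (`0` when `N = 1`).
#' @examples
#' shoulderDose(10, 20)   # ~29.96 Gy
#' @export
setGeneric("shoulderDose", function(object, N) standardGeneric("shoulderDose"))
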