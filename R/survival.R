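#' Single-hit multitarget survival probability
#'
#' \deqn{S(D) = 1 - (1 - e^{-D/D_0})^N}
#' Each of `N` targets is inactivated by single hits with 1/e dose `D0`;
#' the cell dies only when all targets are hit. `S(0) = 1`, `S` is
#' strictly decreasing in dose, and for `N = 1` it reduces to the pure
#' single-hit exponential `exp(-D/D0)`.
#'
#' @param dose Dose(s) in Gy, non-negative.
#' @param D0 Per-target 1/e dose in Gy (> 0).
#' @param N Extrapolation number (>= 1).
#' @return Survival probabilities in `[0, 1]`.
#' @examples
#' survivalProbability(30, D0 = 10, N = 20)  # 1 - (1 - e^-3)^20
#' @export
survivalProbability <- function(dose, D0, N) {
    if (any(dose < 0)) stop("dose must be non-negative")
    stopifnot(D0 > 0, N >= 1)
    1 - (1 - exp(-dose / D0))^N
}

.asSurvivalData <- function(data) {
    nm <- names(data)
    if ("dose_gy" %in% nm) dose <- data$dose_gy
    else if ("dose" %in% nm) dose <- data$dose
    else stop("survival data needs a 'dose_gy' (or 'dose') column")
    if (all(c("n_total", "n_survived") %in% nm)) {
        if (any(data$n_total <= 0))
            stop("n_total must be positive")
        if (any(data$n_survived < 0 | data$n_survived > data$n_total))
            stop("n_survived must lie in [0, n_total]")
        surv <- data$n_survived / data$n_total
    } else if ("survival" %in% nm) {
        surv <- data$survival
    } else {
        stop("survival data needs 'n_total'/'n_survived' or 'survival'")
    }
    data.frame(dose_gy = dose, survival = surv)
}

#' Fit the single-hit multitarget survival model
#'
#' Least-squares fit of `(D0, N)` on the linear survival scale
#' (unweighted), with bounds `D0 > 0`, `N >= 1`, by Levenberg-Marquardt
#' ([minpack.lm::nlsLM]). Starting values come from the terminal
#' log-linear part of the curve: the slope of `log(S)` over the larger
#' doses gives `-1/D0`, and its extrapolation back to dose 0 gives `N`.
#'
#' @param data data.frame with a dose column (`dose_gy` or `dose`) and
#'   either counts (`n_total`, `n_survived`) or a `survival` fraction
#'   column. At least 3 distinct doses are required, and the data must not
#'   be all-survive or all-die (non-identifiable).
#' @param start Optional named list/vector overriding the starting values
#'   `c(D0 = ..., N = ...)`.
#' @return A [MultitargetFit-class] with `D0`, `N`, the shoulder dose
#'   `Dq = D0 * log(N)` and the residual SSE.
#' @examples
#' d <- data.frame(dose_gy = seq(0, 60, 10),
#'                 survival = survivalProbability(seq(0, 60, 10), 10, 20))
#' fitMultitarget(d)
#' @export
fitMultitarget <- function(data, start = NULL) {
    d <- .asSurvivalData(data)
    if (length(unique(d$dose_gy)) < 3L)
        stop("need at least 3 distinct doses to fit the model")
    if (all(d$survival >= 1) || all(d$survival <= 0))
        stop("non-identifiable: all plants survived or all died")
    if (is.null(start)) {
        pos <- d[d$survival > 0 & d$survival < 1 & d$dose_gy > 0, ]
        if (nrow(pos) >= 2) {
            ## terminal slope: emphasize the exponential part of the curve
            cut <- stats::quantile(pos$dose_gy, 0.5)
            tail <- pos[pos$dose_gy >= cut, ]
            if (nrow(tail) < 2) tail <- pos
            fit0 <- lm(log(survival) ~ dose_gy, data = tail)
            slope <- coef(fit0)[["dose_gy"]]
            D0s <- if (is.finite(slope) && slope < 0) -1 / slope
                   else max(d$dose_gy) / 3
            Ns <- max(1, min(exp(coef(fit0)[["(Intercept)"]]), 1e4))
        } else {
            D0s <- max(d$dose_gy) / 3
            Ns <- 10
        }
        start <- list(D0 = D0s, N = Ns)
    } else {
        start <- as.list(start)
    }
    fit <- minpack.lm::nlsLM(
        survival ~ 1 - (1 - exp(-dose_gy / D0))^N,
        data = d, start = start,
        lower = c(D0 = 1e-6, N = 1), upper = c(D0 = Inf, N = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    est <- coef(fit)
    fitted <- survivalProbability(d$dose_gy, est[["D0"]], est[["N"]])
    new("MultitargetFit",
        D0 = est[["D0"]], N = est[["N"]],
        Dq = est[["D0"]] * log(est[["N"]]),
        sse = sum((d$survival - fitted)^2),
        data = d, fitted = fitted)
}

#' @rdname shoulderDose
#' @export
setMethod("shoulderDose", signature(object = "MultitargetFit", N = "missing"),
    function(object) object@D0 * log(object@N))

#' @rdname shoulderDose
#' @export
setMethod("shoulderDose", signature(object = "numeric", N = "numeric"),
    function(object, N) {
        stopifnot(object > 0, N >= 1)
        object * log(N)
    })

setMethod("show", "MultitargetFit", function(object) {
    cat("Single-hit multitarget survival fit\n")
    cat(sprintf("  D0 = %.4g Gy,  N = %.4g,  shoulder dose Dq = %.4g Gy\n",
                object@D0, object@N, object@Dq))
    cat(sprintf("  residual SSE = %.3g on %d doses\n",
                object@sse, nrow(object@data)))
})

#' Plot a dose-survival dataset and its multitarget fit
#'
#' @param fit A [MultitargetFit-class].
#' @param log Plot survival on a log scale (default TRUE, the
#'   radiobiology convention that makes the terminal slope linear).
#' @return Invisibly, `NULL`.
#' @export
plotSurvivalFit <- function(fit, log = TRUE) {
    stopifnot(is(fit, "MultitargetFit"))
    d <- fit@data
    dd <- seq(0, max(d$dose_gy), length.out = 200)
    ss <- survivalProbability(dd, fit@D0, fit@N)
    plot(d$dose_gy, pmax(d$survival, 1e-4), log = if (log) "y" else "",
         xlab = "dose (Gy)", ylab = "survival", pch = 16,
         ylim = if (log) c(max(1e-4, min(ss, d$survival[d$survival > 0])), 1)
                else c(0, 1))
    graphics::lines(dd, pmax(ss, 1e-4), col = "steelblue")
    graphics::abline(v = fit@Dq, lty = 3, col = "firebrick")
    invisible(NULL)
}
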