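#' Evaluate a Hill dose-response curve
#'
#' Computes \code{e0 + (emax - e0) * d^n / (ec50^n + d^n)}, the four-parameter
#' log-logistic response at dose \code{d}. Monotone between \code{e0} (zero
#' dose) and \code{emax} (infinite dose), with the half-effect at
#' \code{d = ec50}.
#'
#' @param hill a [HillCurve-class].
#' @param dose vector of nonnegative concentrations.
#' @return numeric vector of responses.
#' @examples
#' h <- HillCurve(e0 = 1, emax = 0.1, ec50 = 0.5, n = 2)
#' hillResponse(h, c(0, 0.5, 50))
#' @export
hillResponse <- function(hill, dose) {
    stopifnot(is(hill, "HillCurve"))
    if (any(dose < 0)) stop("doses must be >= 0")
    x <- (dose / hill@ec50)^hill@n
    frac <- ifelse(is.infinite(x), 1, x / (1 + x))
    hill@e0 + (hill@emax - hill@e0) * frac
}

#' Invert a Hill curve
#'
#' Returns the dose achieving response \code{y}:
#' \code{ec50 * ((y - e0) / (emax - y))^(1/n)}. Responses outside the open
#' interval between \code{e0} and \code{emax} are unreachable and give
#' \code{Inf} (beyond the asymptote) or 0 (at baseline); used by the Loewe
#' dose-equivalence computation.
#'
#' @param hill a [HillCurve-class].
#' @param y response value(s).
#' @return dose vector (possibly \code{Inf}).
#' @export
hillInverse <- function(hill, y) {
    stopifnot(is(hill, "HillCurve"))
    ratio <- (y - hill@e0) / (hill@emax - y)
    out <- ifelse(ratio > 0, hill@ec50 * ratio^(1 / hill@n),
           ifelse(ratio == 0, 0, Inf))
    out[y == hill@e0] <- 0  # covers the flat-curve 0/0 case
    out
}

#' Fit a Hill curve to monotherapy data
#'
#' Bounded least-squares fit (Levenberg-Marquardt through
#' \code{minpack.lm::nls.lm}) of the four Hill parameters, with a
#' deterministic multi-start over slope initialisations n in {0.5, 1, 2, 4}
#' and EC50 initialised at the median positive dose. Response bounds come
#' from \code{scale}; EC50 is constrained to within a factor 100 of the
#' observed dose range. Flat data (zero response variance) return a constant
#' curve flagged \code{degenerate}.
#'
#' @param dose,response equal-length vectors; doses >= 0, at least 3 distinct
#'   doses.
#' @param scale a [ResponseScale-class] giving the parameter bounds.
#' @return a [HillCurve-class].
#' @examples
#' h <- HillCurve(1, 0.2, 0.3, 1.5)
#' d <- 10^seq(-2, 1, length.out = 6)
#' hillCoef(fitHill(d, hillResponse(h, d)))
#' @export
fitHill <- function(dose, response, scale = responseScale(0, 1)) {
    stopifnot(length(dose) == length(response))
    keep <- is.finite(dose) & is.finite(response)
    dose <- dose[keep]; response <- response[keep]
    if (any(dose < 0)) stop("doses must be >= 0")
    if (length(unique(dose)) < 3L)
        stop("at least 3 distinct doses are required to fit a Hill curve")
    pos <- dose[dose > 0]
    if (length(pos) == 0L) stop("at least one positive dose is required")
    dmin <- min(pos); dmax <- max(pos)

    if (sd(response) < 1e-10) {
        return(HillCurve(e0 = mean(response), emax = mean(response),
                         ec50 = sqrt(dmin * dmax), n = 1, degenerate = TRUE))
    }

    lo <- scale@lo; hi <- scale@hi
    lower <- c(lo, lo, log(dmin) - log(100), log(0.1))
    upper <- c(hi, hi, log(dmax) + log(100), log(10))
    e0Init <- mean(response[dose == min(dose)])
    emaxInit <- mean(response[dose == max(dose)])
    clamp <- function(v, l, u) pmin(pmax(v, l), u)
    resid <- function(par) {
        h <- HillCurve(par[1], par[2], exp(par[3]), exp(par[4]))
        hillResponse(h, dose) - response
    }
    best <- NULL; bestSSE <- Inf
    for (n0 in c(0.5, 1, 2, 4)) {
        par0 <- clamp(c(e0Init, emaxInit, log(median(pos)), log(n0)), lower, upper)
        fit <- try(minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                                      fn = resid,
                                      control = minpack.lm::nls.lm.control(maxiter = 200)),
                   silent = TRUE)
        if (inherits(fit, "try-error")) next
        sse <- sum(fit$fvec^2)
        if (sse < bestSSE) { bestSSE <- sse; best <- fit$par }
    }
    if (is.null(best)) stop("Hill fit failed for all starts")
    HillCurve(e0 = best[1], emax = best[2], ec50 = exp(best[3]), n = exp(best[4]))
}
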