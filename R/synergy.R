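#' Bliss-independent expected inhibition
#'
#' Under Bliss independence the two drugs act as independent probabilistic
#' events on inhibition fractions: \code{fa + fb - fa * fb}.
#'
#' @param fa,fb inhibition fractions in \code{[0, 1]} (inhibition =
#'   1 - response / scale upper bound).
#' @return expected combined inhibition fraction(s).
#' @export
blissExpected <- function(fa, fb) {
    if (any(fa < 0 | fa > 1) || any(fb < 0 | fb > 1))
        stop("inhibition fractions must lie in [0, 1] (clip before calling)")
    fa + fb - fa * fb
}

#' Loewe-additive expected response
#'
#' Solves the dose-equivalence equation \code{d1/D_A(y) + d2/D_B(y) = 1}
#' for the response y, where \code{D_.(y)} is the inverse Hill function
#' ([hillInverse()]), by bisection on a bracketed response range. Boundary
#' doses reduce to the single-drug response; a flat (degenerate) drug
#' contributes no dose equivalent. When no root is bracketed (responses
#' outside both drugs' reach) the nearer boundary response is returned with
#' attribute \code{boundary = TRUE}.
#'
#' @param hillA,hillB monotherapy [HillCurve-class] fits (responses on a
#'   common scale).
#' @param d1,d2 nonnegative doses (scalars).
#' @param tol bisection tolerance in response units.
#' @param maxIter maximum bisection iterations.
#' @return expected response (scalar).
#' @export
loeweExpected <- function(hillA, hillB, d1, d2, tol = 1e-10, maxIter = 200L) {
    stopifnot(length(d1) == 1L, length(d2) == 1L, d1 >= 0, d2 >= 0)
    if (d2 == 0) return(hillResponse(hillA, d1))
    if (d1 == 0) return(hillResponse(hillB, d2))
    flatA <- abs(hillA@emax - hillA@e0) < 1e-12
    flatB <- abs(hillB@emax - hillB@e0) < 1e-12
    if (flatA && flatB) return((hillA@e0 + hillB@e0) / 2)
    if (flatA) return(hillResponse(hillB, d2))
    if (flatB) return(hillResponse(hillA, d1))

    e0 <- (hillA@e0 + hillB@e0) / 2
    dirA <- sign(hillA@emax - e0); dirB <- sign(hillB@emax - e0)
    if (dirA != dirB) {
        # opposing effect directions: additivity towards a common effect is
        # undefined; treat the weaker-displacement drug as inert
        if (abs(hillA@emax - e0) >= abs(hillB@emax - e0))
            return(hillResponse(hillA, d1))
        return(hillResponse(hillB, d2))
    }
    extreme <- if (dirA < 0) min(hillA@emax, hillB@emax) else
        max(hillA@emax, hillB@emax)
    g <- function(y) d1 / hillInverse(hillA, y) + d2 / hillInverse(hillB, y) - 1
    eps <- 1e-9 * abs(e0 - extreme)
    yLo <- e0 + dirA * eps
    yHi <- extreme - dirA * eps
    gLo <- g(yLo); gHi <- g(yHi)
    if (!is.finite(gLo) || !is.finite(gHi) || sign(gLo) == sign(gHi)) {
        out <- if (is.finite(gHi) && abs(gHi) < abs(gLo)) yHi else yLo
        attr(out, "boundary") <- TRUE
        return(out)
    }
    # bisection: g is monotone from +Inf (near baseline) to < 0 (near Ef)
    for (i in seq_len(maxIter)) {
        mid <- (yLo + yHi) / 2
        if (abs(yHi - yLo) < tol) break
        if (sign(g(mid)) == sign(gLo)) { yLo <- mid; gLo <- g(mid) }
        else yHi <- mid
    }
    (yLo + yHi) / 2
}

#' Synergy score of a measured or predicted surface
#'
#' Per combination cell (both doses > 0) the excess of the null-model
#' expected response over the observed response is computed — positive means
#' the observed growth fell below expectation, i.e. synergy — and the score
#' is the mean excess over the surface's combination cells, in the surface's
#' response units. Expectations come from the supplied monotherapy Hill fits
#' (unit scale), under Bliss independence or Loewe additivity.
#'
#' @param surface a [ResponseSurface-class].
#' @param hillA,hillB monotherapy [HillCurve-class] fits on the unit scale.
#' @param model \code{"bliss"} or \code{"loewe"}.
#' @return one-row data.frame: cell, drugA, drugB, model, value, nCells.
#' @export
surfaceSynergy <- function(surface, hillA, hillB, model = c("bliss", "loewe")) {
    model <- match.arg(model)
    comboA <- surface@dosesA > 0; comboB <- surface@dosesB > 0
    da <- surface@dosesA[comboA]; db <- surface@dosesB[comboB]
    obs <- surface@values[comboA, comboB, drop = FALSE]
    if (length(obs) == 0L) stop("surface has no combination dose pairs")
    sc <- surface@scale
    expected <- matrix(NA_real_, length(da), length(db))
    for (i in seq_along(da)) for (j in seq_along(db)) {
        if (model == "bliss") {
            fa <- 1 - hillResponse(hillA, da[i])
            fb <- 1 - hillResponse(hillB, db[j])
            e <- 1 - blissExpected(min(max(fa, 0), 1), min(max(fb, 0), 1))
        } else {
            e <- as.numeric(loeweExpected(hillA, hillB, da[i], db[j]))
        }
        expected[i, j] <- sc@lo + e * (sc@hi - sc@lo)
    }
    ok <- is.finite(obs)
    if (!any(ok)) stop("surface has no measured combination cells")
    data.frame(cell = surface@cell, drugA = surface@drugA,
               drugB = surface@drugB, model = model,
               value = mean(expected[ok] - obs[ok]), nCells = sum(ok))
}

#' Evaluate predicted surfaces against ground truth
#'
#' Pools all matched response values and reports Pearson and Spearman
#' correlations plus per-surface root mean squared errors.
#'
#' @param predicted,truth lists of [ResponseSurface-class] objects, matched
#'   by position (identical triplets and grids).
#' @return list: \code{pearson}, \code{spearman}, \code{rmse} (per-surface
#'   vector), \code{rmseMean}, \code{n} (pooled value count).
#' @export
evaluatePredictions <- function(predicted, truth) {
    stopifnot(length(predicted) == length(truth), length(truth) > 0L)
    predAll <- c(); trueAll <- c(); rmse <- numeric(length(truth))
    for (i in seq_along(truth)) {
        p <- predicted[[i]]; y <- truth[[i]]
        if (!identical(unname(surfaceTriplet(p)), unname(surfaceTriplet(y))))
            stop(sprintf("surface %d: triplet mismatch", i))
        ok <- is.finite(y@values) & is.finite(p@values)
        predAll <- c(predAll, p@values[ok]); trueAll <- c(trueAll, y@values[ok])
        rmse[i] <- sqrt(mean((p@values[ok] - y@values[ok])^2))
    }
    if (length(trueAll) < 2L) stop("need at least 2 matched response values")
    list(pearson = cor(predAll, trueAll),
         spearman = cor(predAll, trueAll, method = "spearman"),
         rmse = rmse, rmseMean = mean(rmse), n = length(trueAll))
}
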