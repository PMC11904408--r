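## BRAID surface evaluation and fitting.
##
## Parametrization: with shared baseline E0 (mean of the two monotherapy
## baselines), per-drug asymptotes EfA/EfB from the monotherapy fits and the
## overall asymptote Ef the one furthest from E0, define for each drug the
## rescaled effective dose
##     Dt_i = F_i x_i / (1 + (1 - F_i) x_i),   x_i = (d_i / ec50_i)^{n_i},
##     F_i  = (Ef_i - E0) / (Ef - E0),
## and combine with the interaction pair (kappa, delta), h = delta*sqrt(nA nB):
##     D = Dt_A^{1/h} + Dt_B^{1/h} + kappa * sqrt(Dt_A^{1/h} Dt_B^{1/h})
##     E(d1, d2) = E0 + (Ef - E0) * D^h / (1 + D^h).
## kappa = 0, delta = 1 reduces to Loewe additivity of the (extended) Hill
## curves; each axis reduces exactly to its monotherapy Hill curve.

.braidPieces <- function(bs) {
    hA <- bs@hillA; hB <- bs@hillB
    e0 <- (hA@e0 + hB@e0) / 2
    dA <- abs(hA@emax - e0); dB <- abs(hB@emax - e0)
    ef <- if (dA >= dB) hA@emax else hB@emax
    list(hA = hA, hB = hB, e0 = e0, ef = ef)
}

#' Evaluate a BRAID combination surface
#'
#' Response of the two-drug BRAID surface at concentration pairs
#' \code{(d1, d2)} (vectorized, recycled). At \code{d2 = 0} the surface
#' reduces exactly to drug A's Hill curve (and symmetrically); at
#' \code{kappa = 0, delta = 1} it is the additive, Loewe-consistent surface
#' implied by the two monotherapy curves.
#'
#' @param bs a [BraidSurface-class].
#' @param d1,d2 nonnegative concentrations of drug A and drug B.
#' @return numeric vector of responses.
#' @seealso [braidGrid()], [neutralSurface()]
#' @export
braidResponse <- function(bs, d1, d2) {
    stopifnot(is(bs, "BraidSurface"))
    if (any(d1 < 0) || any(d2 < 0)) stop("doses must be >= 0")
    p <- .braidPieces(bs)
    if (abs(p$ef - p$e0) < 1e-12)           # both drugs flat: constant surface
        return(rep(p$e0, length(d1 + d2)))
    fA <- (p$hA@emax - p$e0) / (p$ef - p$e0)
    fB <- (p$hB@emax - p$e0) / (p$ef - p$e0)
    # BRAID assumes both effects point towards Ef; an opposing drug is
    # treated as inert on this surface
    fA <- min(max(fA, 0), 1); fB <- min(max(fB, 0), 1)
    xA <- (d1 / p$hA@ec50)^p$hA@n
    xB <- (d2 / p$hB@ec50)^p$hB@n
    dtA <- ifelse(is.infinite(xA),
                  if (fA < 1) fA / (1 - fA) else Inf,
                  fA * xA / (1 + (1 - fA) * xA))
    dtB <- ifelse(is.infinite(xB),
                  if (fB < 1) fB / (1 - fB) else Inf,
                  fB * xB / (1 + (1 - fB) * xB))
    h <- bs@delta * sqrt(p$hA@n * p$hB@n)
    uA <- dtA^(1 / h); uB <- dtB^(1 / h)
    cross <- ifelse(uA == 0 | uB == 0, 0, sqrt(uA * uB))
    D <- pmax(uA + uB + bs@kappa * cross, 0)
    p$e0 + (p$ef - p$e0) * plogis(h * log(D))
}

#' @rdname braidResponse
#' @param dosesA,dosesB dose vectors spanning a rectangular grid.
#' @return \code{braidGrid}: response matrix with rows following
#'   \code{dosesA}.
#' @export
braidGrid <- function(bs, dosesA, dosesB) {
    g <- expand.grid(a = dosesA, b = dosesB)
    matrix(braidResponse(bs, g$a, g$b), nrow = length(dosesA))
}

#' The additive (neutral) surface of two monotherapy curves
#'
#' The BRAID surface with \code{kappa = 0, delta = 1}: no interaction, fully
#' determined by the two Hill curves. This is the no-learning baseline and
#' the reference from which difference surfaces are measured.
#'
#' @param hillA,hillB [HillCurve-class] objects.
#' @return a [BraidSurface-class].
#' @export
neutralSurface <- function(hillA, hillB)
    BraidSurface(hillA = hillA, hillB = hillB, kappa = 0, delta = 1)

#' Difference to the neutral surface
#'
#' \code{differenceResponse} evaluates \code{S(kappa) - S(0)}, the deviation
#' of the surface from the additive surface implied by its own monotherapy
#' curves; adding the neutral surface back restores the full surface exactly.
#'
#' @inheritParams braidResponse
#' @return numeric vector of response differences.
#' @export
differenceResponse <- function(bs, d1, d2)
    braidResponse(bs, d1, d2) -
        braidResponse(neutralSurface(bs@hillA, bs@hillB), d1, d2)

#' Canonical EC50-relative normalization grid
#'
#' The fixed 8x8 grid on which surfaces are sampled for kernel comparison:
#' doses at multiples {1/64, 1/16, 1/4, 1/2, 1, 2, 4, 16} of each drug's
#' EC50. Placing the grid relative to potency makes surfaces of drugs with
#' very different potency ranges comparable.
#'
#' @param hillA,hillB [HillCurve-class] objects supplying the EC50s.
#' @return list with components \code{a} and \code{b} (dose vectors).
#' @export
canonicalGrid <- function(hillA, hillB) {
    m <- c(1/64, 1/16, 1/4, 1/2, 1, 2, 4, 16)
    list(a = m * hillA@ec50, b = m * hillB@ec50)
}

#' Normalize a surface for kernel comparison
#'
#' Samples the surface on the canonical EC50-relative 8x8 grid
#' ([canonicalGrid()]), rescales responses to the unit interval through
#' \code{scale}, and flattens row-major (drug A axis varies slowest) to a
#' length-64 vector. In difference mode the normalized neutral surface is
#' subtracted, so the vector is the normalized deviation from additivity
#' (zero for \code{kappa = 0, delta = 1}).
#'
#' @param bs a [BraidSurface-class] (parameters on the \code{scale} given).
#' @param mode \code{"direct"} or \code{"difference"}.
#' @param scale the [ResponseScale-class] the parameters live on.
#' @return numeric vector of length 64.
#' @export
normalizeSurface <- function(bs, mode = c("direct", "difference"),
                             scale = responseScale(0, 1)) {
    mode <- match.arg(mode)
    grid <- canonicalGrid(bs@hillA, bs@hillB)
    vals <- braidGrid(bs, grid$a, grid$b)
    if (any(!is.finite(vals))) {
        bad <- which(!is.finite(vals), arr.ind = TRUE)[1, ]
        stop(sprintf("non-finite surface value at doses (%g, %g)",
                     grid$a[bad[1]], grid$b[bad[2]]))
    }
    out <- (vals - scale@lo) / (scale@hi - scale@lo)
    if (mode == "difference") {
        neu <- braidGrid(neutralSurface(bs@hillA, bs@hillB), grid$a, grid$b)
        out <- out - (neu - scale@lo) / (scale@hi - scale@lo)
    }
    as.vector(t(out))
}

# row-major 8x8 transpose permutation of a normalized vector: the same
# surface seen with the two drugs swapped
.transposeVec <- function(v, n = 8L) as.vector(matrix(v, n, n, byrow = TRUE))

#' Fit BRAID interaction parameters to a measured surface
#'
#' Fits only the interaction pair (kappa, delta) by bounded
#' Levenberg-Marquardt least squares, with the monotherapy Hill curves held
#' fixed at their separately fitted values (the model's accuracy rests on
#' good monotherapy estimates, and the additive baseline must share them).
#' A deterministic multi-start over a fixed kappa initialisation grid makes
#' the fit reproducible. Zero-dose rows/columns are excluded from the
#' interaction fit. Degenerate (both-flat) monotherapy returns the neutral
#' parameters with a flag.
#'
#' @param surface a [ResponseSurface-class] (raw responses; NA cells allowed).
#' @param hillA,hillB fixed monotherapy [HillCurve-class] fits on the
#'   internal unit scale.
#' @param kappaStarts deterministic initialisation grid for kappa.
#' @return a [BraidSurface-class].
#' @examples
#' hA <- HillCurve(1, 0.2, 0.5, 1.5); hB <- HillCurve(1, 0.35, 1.2, 2)
#' truth <- BraidSurface(hA, hB, kappa = 2.5, delta = 1)
#' d <- c(0.1, 0.4, 1.6, 6.4)
#' surf <- responseSurface("c", "a", "b", d, d, braidGrid(truth, d, d))
#' braidCoef(fitBraid(surf, hA, hB))[c("kappa", "delta")]
#' @export
fitBraid <- function(surface, hillA, hillB,
                     kappaStarts = c(-1.5, -0.5, 0, 0.5, 1.5, 3)) {
    stopifnot(is(surface, "ResponseSurface"))
    comboA <- surface@dosesA > 0; comboB <- surface@dosesB > 0
    vals <- surface@values[comboA, comboB, drop = FALSE]
    # rescale observations to the unit scale the Hill fits live on
    vals <- (vals - surface@scale@lo) / (surface@scale@hi - surface@scale@lo)
    g <- expand.grid(a = surface@dosesA[comboA], b = surface@dosesB[comboB])
    ok <- is.finite(as.vector(vals))
    if (sum(ok) < 4L) stop("at least 4 measured combination cells are required")
    obs <- as.vector(vals)[ok]; da <- g$a[ok]; db <- g$b[ok]

    e0 <- (hillA@e0 + hillB@e0) / 2
    if (abs(hillA@emax - e0) < 1e-9 && abs(hillB@emax - e0) < 1e-9)
        return(BraidSurface(hillA, hillB, kappa = 0, delta = 1, degenerate = TRUE))

    # Optimize u = log(kappa + 2), v = log(delta), bounded to the modeled
    # interaction range. Two identifiability safeguards for small noisy
    # grids, where kappa and delta are nearly collinear: (i) the kappa-only
    # (delta = 1) and (kappa, delta) fits are compared by BIC, freeing delta
    # only when the data support it; (ii) a noise-calibrated ridge pulls the
    # interaction parameters toward neutrality — the penalty weight is
    # proportional to the residual noise of the unpenalized fit, so exact
    # data are fitted without bias while weakly identified surfaces shrink
    # toward additivity.
    lower <- c(log(0.05), log(0.2)); upper <- c(log(12), log(5))
    ctrl <- minpack.lm::nls.lm.control(maxiter = 150)
    nObs <- length(obs)
    fitPass <- function(w) {
        resid <- function(par) {
            bs <- BraidSurface(hillA, hillB, kappa = exp(par[1]) - 2,
                               delta = if (length(par) > 1L) exp(par[2]) else 1)
            c(braidResponse(bs, da, db) - obs,
              w * (par[1] - log(2)), if (length(par) > 1L) w * par[2])
        }
        best <- NULL; bestBIC <- Inf; bestRSS <- NA_real_
        for (nPar in 1:2) {
            bestPar <- NULL; bestSSE <- Inf
            for (k0 in kappaStarts) {
                par0 <- c(log(k0 + 2), 0)[seq_len(nPar)]
                fit <- try(suppressWarnings(minpack.lm::nls.lm(
                    par = par0, lower = lower[seq_len(nPar)],
                    upper = upper[seq_len(nPar)], fn = resid, control = ctrl)),
                    silent = TRUE)
                if (inherits(fit, "try-error")) next
                sse <- sum(fit$fvec^2)
                if (sse < bestSSE - 1e-14) { bestSSE <- sse; bestPar <- fit$par }
            }
            if (is.null(bestPar)) next
            rss <- sum((braidResponse(BraidSurface(
                hillA, hillB, kappa = exp(bestPar[1]) - 2,
                delta = if (nPar > 1L) exp(bestPar[2]) else 1), da, db) -
                obs)^2)
            bic <- nObs * log(max(rss, 1e-14) / nObs) + nPar * log(nObs)
            if (bic < bestBIC) { bestBIC <- bic; best <- bestPar; bestRSS <- rss }
        }
        if (is.null(best)) stop("BRAID interaction fit failed for all starts")
        list(par = best, rss = bestRSS)
    }
    stage1 <- fitPass(0)
    sigmaHat <- sqrt(stage1$rss / max(nObs - length(stage1$par), 1L))
    best <- if (sigmaHat > 1e-8) fitPass(4 * sigmaHat)$par else stage1$par
    BraidSurface(hillA, hillB, kappa = exp(best[1]) - 2,
                 delta = if (length(best) > 1L) exp(best[2]) else 1)
}
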