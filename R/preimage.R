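#' Default candidate grid for the interaction strength
#'
#' 25 values log-symmetrically placed around additivity, spanning strong
#' antagonism (-1.9, near the BRAID domain edge) to strong synergy (8).
#'
#' @return numeric vector of length 25 containing 0.
#' @export
kappaGridDefault <- function()
    c(-rev(exp(seq(log(0.05), log(1.9), length.out = 8))), 0,
      exp(seq(log(0.05), log(8), length.out = 16)))

# candidate parameter table in deterministic order
.candidateTable <- function(kappaGrid, deltaGrid)
    expand.grid(delta = deltaGrid, kappa = kappaGrid)[, c("kappa", "delta")]

# inner products <g, psi(y)> for rows of a vector matrix; g2, if given, adds
# the swapped-ordering term evaluated at the transposed surfaces
.preimageObjective <- function(map, vecs, g1, g2 = NULL) {
    obj <- drop(embedSurface(map, vecs) %*% g1)
    if (!is.null(g2)) {
        vecsT <- t(apply(vecs, 1, .transposeVec))
        obj <- obj + drop(embedSurface(map, vecsT) %*% g2)
    }
    obj
}

#' Candidate-set pre-image solver
#'
#' Builds one BRAID candidate surface per (kappa, delta) grid point from the
#' query triplet's own monotherapy curves, embeds each with the Nystrom map
#' and returns the candidate maximising the inner product with the predicted
#' embedding. Ties are broken towards neutrality: smallest |kappa|, then
#' smallest grid index. When a second embedding for the swapped drug
#' ordering is supplied, the objective sums both orderings, which makes the
#' choice order-equivariant.
#'
#' @param embedding predicted output embedding \code{g(x)} (length
#'   \code{effectiveDim(map)}).
#' @param map a [NystromMap-class].
#' @param hillA,hillB the query triplet's monotherapy [HillCurve-class] fits.
#' @param kappaGrid,deltaGrid non-empty candidate grids.
#' @param mode \code{"direct"} or \code{"difference"} — must match the mode
#'   the map's landmarks were built in.
#' @param embeddingSwapped optional embedding predicted for the
#'   \code{(cell, drugB, drugA)} ordering.
#' @return list with \code{params} ([BraidSurface-class]), \code{objective},
#'   \code{kappa}, \code{delta}.
#' @export
candidatePreimage <- function(embedding, map, hillA, hillB,
                              kappaGrid = kappaGridDefault(),
                              deltaGrid = 1,
                              mode = c("difference", "direct"),
                              embeddingSwapped = NULL) {
    mode <- match.arg(mode)
    if (length(kappaGrid) == 0L || length(deltaGrid) == 0L)
        stop("candidate grids must be non-empty")
    tab <- .candidateTable(kappaGrid, deltaGrid)
    cand <- lapply(seq_len(nrow(tab)), function(i)
        BraidSurface(hillA, hillB, kappa = tab$kappa[i], delta = tab$delta[i]))
    vecs <- t(vapply(cand, normalizeSurface, numeric(64), mode = mode))
    obj <- .preimageObjective(map, vecs, embedding, embeddingSwapped)
    best <- max(obj)
    idx <- which(obj >= best - 1e-12)
    idx <- idx[order(abs(tab$kappa[idx]), idx)][1]
    list(params = cand[[idx]], objective = obj[idx],
         kappa = tab$kappa[idx], delta = tab$delta[idx])
}

# gradient of z -> <g, psi(z)> for the RBF Nystrom map:
# sum_i w_i k(z, l_i) (l_i - z) / sigma^2, w = V_r Lambda_r^{-1/2} g
.embedGradient <- function(map, z, w) {
    k <- drop(rbfKernel(matrix(z, 1), map@landmarks@vectors, sigma = map@sigma))
    wk <- w * k
    drop(crossprod(map@landmarks@vectors, wk) - sum(wk) * z) / map@sigma^2
}

#' Projected gradient-descent pre-image solver
#'
#' Optimizes the free surface vector z (samples on the canonical 8x8 grid)
#' to maximise the embedding inner product with Nesterov-accelerated Adam
#' (Nadam) updates and an analytic RBF gradient, then projects the
#' end-result back onto valid surfaces by fitting the BRAID interaction
#' parameters to it ([fitBraid()]). The start is the neutral surface in
#' direct mode and the zero function in difference mode. As a safeguard the
#' projected solution is never returned if it scores below the neutral
#' start; projection failure falls back to the candidate-set solver. Fully
#' deterministic.
#'
#' @inheritParams candidatePreimage
#' @param steps,lr Nadam step count and learning rate.
#' @param beta1,beta2 Nadam moment decay rates.
#' @return list as in [candidatePreimage()], plus \code{objectiveInit}.
#' @export
pgdPreimage <- function(embedding, map, hillA, hillB,
                        mode = c("difference", "direct"),
                        steps = 200L, lr = 0.05,
                        beta1 = 0.9, beta2 = 0.999,
                        embeddingSwapped = NULL) {
    mode <- match.arg(mode)
    if (any(!is.finite(embedding))) stop("embedding must be finite")
    neutral <- neutralSurface(hillA, hillB)
    neutralVec <- normalizeSurface(neutral, "direct")
    z <- if (mode == "direct") neutralVec else numeric(64)

    w1 <- drop(map@eigvecs %*% (embedding / sqrt(map@eigvals)))
    w2 <- if (!is.null(embeddingSwapped))
        drop(map@eigvecs %*% (embeddingSwapped / sqrt(map@eigvals))) else NULL
    grad <- function(z) {
        g <- .embedGradient(map, z, w1)
        if (!is.null(w2))
            g <- g + .transposeVec(.embedGradient(map, .transposeVec(z), w2))
        g
    }

    m <- numeric(64); v <- numeric(64); eps <- 1e-8
    for (t in seq_len(steps)) {
        g <- grad(z)
        if (any(!is.finite(g))) stop("non-finite gradient in pre-image descent")
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        # Nadam: Nesterov look-ahead on the first moment; ascent direction.
        # The rate anneals linearly so the iterate settles instead of
        # oscillating at the terminal step size.
        lrt <- lr * (1 - (t - 1) / steps)
        z <- z + lrt * (beta1 * mhat + (1 - beta1) * g / (1 - beta1^t)) /
            (sqrt(vhat) + eps)
    }

    scoreParams <- function(bs) {
        vec <- normalizeSurface(bs, mode)
        v1 <- sum(embedding * embedSurface(map, vec))
        if (!is.null(embeddingSwapped))
            v1 <- v1 + sum(embeddingSwapped *
                           embedSurface(map, .transposeVec(vec)))
        v1
    }
    objInit <- scoreParams(neutral)

    grid <- canonicalGrid(hillA, hillB)
    target <- if (mode == "difference") z + neutralVec else z
    projected <- try({
        surf <- responseSurface("query", "A", "B", grid$a, grid$b,
                                matrix(target, 8, 8, byrow = TRUE))
        fitBraid(surf, hillA, hillB)
    }, silent = TRUE)
    objProj <- if (inherits(projected, "try-error")) NA_real_ else
        scoreParams(projected)
    if (!is.finite(objProj) || objProj < objInit - 1e-12) {
        # projection failure (the fit errored, or lost the ascent the
        # descent had achieved): fall back to the candidate-set solution,
        # whose grid contains the neutral start
        out <- candidatePreimage(embedding, map, hillA, hillB, mode = mode,
                                 embeddingSwapped = embeddingSwapped)
        out$objectiveInit <- objInit
        return(out)
    }
    list(params = projected, objective = objProj, objectiveInit = objInit,
         kappa = projected@kappa, delta = projected@delta)
}

#' Assemble a response-surface prediction from fitted parameters
#'
#' Evaluates the BRAID surface on the query dose grid (in difference mode
#' the predicted deviation plus the neutral surface — which by construction
#' is the full BRAID surface of the recovered parameters), rescales to the
#' dataset response scale and clips to its bounds.
#'
#' @param params a [BraidSurface-class] on the internal unit scale.
#' @param cell,drugA,drugB identifiers for the returned surface.
#' @param dosesA,dosesB query dose grid.
#' @param scale target [ResponseScale-class].
#' @param mode prediction mode (kept for provenance; both modes evaluate the
#'   full recovered surface).
#' @return a [ResponseSurface-class].
#' @export
assemblePrediction <- function(params, cell, drugA, drugB, dosesA, dosesB,
                               scale = responseScale(0, 1),
                               mode = c("difference", "direct")) {
    mode <- match.arg(mode)
    vals <- braidGrid(params, dosesA, dosesB)
    vals <- scale@lo + vals * (scale@hi - scale@lo)
    vals <- pmin(pmax(vals, scale@lo), scale@hi)
    responseSurface(cell, drugA, drugB, dosesA, dosesB, vals, scale)
}
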