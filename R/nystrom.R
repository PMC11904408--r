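#' Default Hill archetype pairs for landmark generation
#'
#' Four deterministic pairs of monotherapy shapes spanning strong/weak
#' efficacy and steep/shallow slopes. On the EC50-relative canonical grid a
#' surface's normalized vector depends only on (e0, emax, n), so archetype
#' EC50s are fixed at 1.
#'
#' @return list of length-2 lists of [HillCurve-class] objects.
#' @export
defaultArchetypes <- function() {
    strongSteep   <- HillCurve(1, 0.05, 1, 2.5)
    strongShallow <- HillCurve(1, 0.10, 1, 0.8)
    moderate      <- HillCurve(1, 0.40, 1, 1.5)
    weak          <- HillCurve(1, 0.70, 1, 1.0)
    list(list(strongSteep, strongSteep),
         list(strongSteep, weak),
         list(moderate, moderate),
         list(strongShallow, moderate))
}

#' Generate a deterministic set of landmark surfaces
#'
#' Builds the Cartesian product of Hill archetype pairs x kappa grid x delta
#' grid, normalizes every surface with [normalizeSurface()] and returns them
#' in deterministic order. These landmarks anchor the Nystrom approximation
#' of the output kernel; the defaults cover antagonistic through strongly
#' synergistic interactions.
#'
#' @param archetypes list of Hill curve pairs, see [defaultArchetypes()].
#' @param kappaGrid,deltaGrid interaction parameter grids (non-empty).
#' @param mode target mode, \code{"direct"} or \code{"difference"}.
#' @return a [LandmarkSet-class].
#' @export
generateLandmarks <- function(archetypes = defaultArchetypes(),
                              kappaGrid = c(-1.5, -0.5, 0, 0.5, 1.5, 3),
                              deltaGrid = c(0.5, 1, 2),
                              mode = c("difference", "direct")) {
    mode <- match.arg(mode)
    if (length(archetypes) == 0L || length(kappaGrid) == 0L ||
        length(deltaGrid) == 0L)
        stop("archetypes, kappaGrid and deltaGrid must be non-empty")
    params <- list(); vecs <- list(); i <- 0L
    for (pair in archetypes) for (k in kappaGrid) for (d in deltaGrid) {
        i <- i + 1L
        bs <- BraidSurface(pair[[1]], pair[[2]], kappa = k, delta = d)
        params[[i]] <- bs
        vecs[[i]] <- normalizeSurface(bs, mode)
    }
    new("LandmarkSet", vectors = do.call(rbind, vecs), params = params,
        mode = mode)
}

#' Build the Nystrom-approximated output feature map
#'
#' Forms the RBF Gram matrix of the landmark vectors, eigendecomposes it and
#' retains the eigenpairs with eigenvalue >= \code{eigThreshold}; the induced
#' feature map is \code{psi(y) = Lambda_r^{-1/2} V_r^t k(y, L)}. Truncation
#' keeps the inverse square root numerically stable; the retained count is
#' the effective output dimension. With all eigenvalues retained the
#' embedding inner products reproduce the kernel exactly on the landmarks.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param eigThreshold eigenvalue cutoff (default 0.1).
#' @param sigma output-kernel bandwidth; default [sigmaHeuristic()] over the
#'   landmark vectors.
#' @return a [NystromMap-class].
#' @export
buildNystromMap <- function(landmarks, eigThreshold = 0.1, sigma = NULL) {
    stopifnot(is(landmarks, "LandmarkSet"))
    if (is.null(sigma)) sigma <- sigmaHeuristic(landmarks@vectors)
    K <- rbfKernel(landmarks@vectors, sigma = sigma)
    eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- eig$values >= eigThreshold
    if (!any(keep))
        stop(sprintf("no eigenvalue >= threshold %g; lower eigThreshold",
                     eigThreshold))
    new("NystromMap", landmarks = landmarks, sigma = sigma,
        eigvals = eig$values[keep],
        eigvecs = eig$vectors[, keep, drop = FALSE],
        effectiveDim = sum(keep), threshold = eigThreshold)
}

#' Embed normalized surfaces into the approximated output space
#'
#' \code{psi(y) = Lambda_r^{-1/2} V_r^t k(y, L)}: the Nystrom feature vector
#' of a normalized surface. Since the output kernel is normalized,
#' \code{||psi(y)|| <= 1} up to truncation error.
#'
#' @param map a [NystromMap-class].
#' @param y a normalized surface vector (length matching the landmarks) or a
#'   matrix of them (rows).
#' @return embedding vector of length \code{effectiveDim(map)}, or a matrix
#'   with one embedding per row.
#' @export
embedSurface <- function(map, y) {
    stopifnot(is(map, "NystromMap"))
    vec <- is.null(dim(y))
    if (vec) y <- matrix(y, nrow = 1)
    if (ncol(y) != ncol(map@landmarks@vectors))
        stop("surface vector length does not match the landmark vectors")
    k <- rbfKernel(y, map@landmarks@vectors, sigma = map@sigma)
    psi <- k %*% sweep(map@eigvecs, 2, sqrt(map@eigvals), "/")
    if (vec) drop(psi) else psi
}

#' Serialize / restore a landmark set
#'
#' Landmark sets are written as JSON (generating parameters, mode and the
#' normalized vectors) so a model's output space is reproducible outside R.
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path file path.
#' @return \code{readLandmarks} returns a [LandmarkSet-class].
#' @export
writeLandmarks <- function(landmarks, path) {
    par <- lapply(landmarks@params, function(p) as.list(braidCoef(p)))
    jsonlite::write_json(
        list(mode = landmarks@mode, params = par,
             vectors = unname(apply(landmarks@vectors, 1, as.numeric,
                                    simplify = FALSE))),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- lapply(seq_len(nrow(x$params)), function(i) {
        p <- x$params[i, ]
        BraidSurface(HillCurve(p$e0_a, p$emax_a, p$ec50_a, p$n_a),
                     HillCurve(p$e0_b, p$emax_b, p$ec50_b, p$n_b),
                     kappa = p$kappa, delta = p$delta)
    })
    vecs <- if (is.list(x$vectors)) do.call(rbind, x$vectors) else x$vectors
    new("LandmarkSet", vectors = vecs, params = params, mode = x$mode)
}
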