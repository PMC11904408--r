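#' Extract curve or surface coefficients
#'
#' \code{hillCoef} returns the four Hill parameters as a named numeric
#' vector; \code{braidCoef} returns the interaction pair together with both
#' monotherapy parameter sets.
#'
#' @param object a [HillCurve-class] or [BraidSurface-class].
#' @return named numeric vector.
#' @export
setGeneric("hillCoef", function(object) standardGeneric("hillCoef"))

#' @rdname hillCoef
#' @export
setGeneric("braidCoef", function(object) standardGeneric("braidCoef"))

#' @rdname hillCoef
#' @export
setMethod("hillCoef", "HillCurve", function(object)
    c(e0 = object@e0, emax = object@emax, ec50 = object@ec50, n = object@n))

#' @rdname hillCoef
#' @export
setMethod("braidCoef", "BraidSurface", function(object) {
    a <- hillCoef(object@hillA); b <- hillCoef(object@hillB)
    names(a) <- paste0(names(a), "_a"); names(b) <- paste0(names(b), "_b")
    c(kappa = object@kappa, delta = object@delta, a, b)
})

#' Accessors for response surfaces
#'
#' @param object a [ResponseSurface-class].
#' @return \code{responseValues}: the response matrix; \code{doses}: list
#'   with elements \code{a} and \code{b}; \code{surfaceTriplet}: named
#'   character vector of the (cell, drug A, drug B) identifiers.
#' @export
setGeneric("responseValues", function(object) standardGeneric("responseValues"))

#' @rdname responseValues
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))

#' @rdname responseValues
#' @export
setGeneric("surfaceTriplet", function(object) standardGeneric("surfaceTriplet"))

#' @rdname responseValues
#' @export
setMethod("responseValues", "ResponseSurface", function(object) object@values)

#' @rdname responseValues
#' @export
setMethod("doses", "ResponseSurface", function(object)
    list(a = object@dosesA, b = object@dosesB))

#' @rdname responseValues
#' @export
setMethod("surfaceTriplet", "ResponseSurface", function(object)
    c(cell = object@cell, drugA = object@drugA, drugB = object@drugB))

#' Accessors for the Nystrom output map
#'
#' @param object a [NystromMap-class].
#' @return \code{effectiveDim}: retained rank; \code{landmarkVectors}: the
#'   matrix of normalized landmark surfaces; \code{gramInvSqrt}: the
#'   symmetric truncated inverse square root of the landmark Gram matrix.
#' @export
setGeneric("effectiveDim", function(object) standardGeneric("effectiveDim"))

#' @rdname effectiveDim
#' @export
setGeneric("landmarkVectors", function(object) standardGeneric("landmarkVectors"))

#' @rdname effectiveDim
#' @export
setGeneric("gramInvSqrt", function(object) standardGeneric("gramInvSqrt"))

#' @rdname effectiveDim
#' @export
setMethod("effectiveDim", "NystromMap", function(object) object@effectiveDim)

#' @rdname effectiveDim
#' @export
setMethod("landmarkVectors", "NystromMap", function(object)
    object@landmarks@vectors)

#' @rdname effectiveDim
#' @export
setMethod("gramInvSqrt", "NystromMap", function(object)
    object@eigvecs %*% (t(object@eigvecs) / sqrt(object@eigvals)))

#' @rdname effectiveDim
#' @param ... unused.
#' @export
setMethod("dim", "SampledKronOperator", function(x)
    rep(length(x@rowsA), 2L))

setMethod("show", "HillCurve", function(object) {
    cat(sprintf("HillCurve: e0=%.4g emax=%.4g ec50=%.4g n=%.4g%s\n",
        object@e0, object@emax, object@ec50, object@n,
        if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "BraidSurface", function(object) {
    cat(sprintf("BraidSurface: kappa=%.4g delta=%.4g%s\n",
        object@kappa, object@delta,
        if (object@degenerate) " [degenerate]" else ""))
    cat("  drug A "); show(object@hillA)
    cat("  drug B "); show(object@hillB)
})

setMethod("show", "ResponseSurface", function(object) {
    cat(sprintf("ResponseSurface %s | %s + %s: %d x %d grid on [%g, %g]\n",
        object@cell, object@drugA, object@drugB,
        length(object@dosesA), length(object@dosesB),
        object@scale@lo, object@scale@hi))
})

setMethod("show", "SampledKronOperator", function(object) {
    cat(sprintf("SampledKronOperator: %d samples from a (%d x %d) kron (%d x %d) product\n",
        length(object@rowsA), nrow(object@factorA), nrow(object@factorA),
        nrow(object@factorB), nrow(object@factorB)))
})

setMethod("show", "NystromMap", function(object) {
    cat(sprintf("NystromMap: %d landmarks (%s mode), sigma=%.4g, rank %d (threshold %g)\n",
        nrow(object@landmarks@vectors), object@landmarks@mode, object@sigma,
        object@effectiveDim, object@threshold))
})

setMethod("show", "KrrDualModel", function(object) {
    cat(sprintf("KrrDualModel: %d samples x %d embedding dims, %d CG iterations (lambda=%g)\n",
        nrow(object@coeffs), ncol(object@coeffs), object@iterations,
        object@lambda))
})

setMethod("show", "SurfaceKRModel", function(object) {
    cfg <- object@config
    cat(sprintf("SurfaceKRModel (%s scope): mode=%s, pre-image solver=%s\n",
        cfg$scope, cfg$mode, cfg$solver))
    cat(sprintf("  %d cell lines, %d drugs, %d training surfaces\n",
        length(object@cellIds), length(object@drugIds), length(object@surfaces)))
    if (!is.null(object@map)) show(object@map)
})
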