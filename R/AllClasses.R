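#' @import methods
#' @importFrom stats median sd cor rnorm runif rbinom plogis aggregate
#' @importFrom utils read.csv write.csv
NULL

#' Response scale of a dose-response dataset
#'
#' Declares the bounds of the measured response, typically \code{[0, 1]} for
#' viability fractions or \code{[0, 100]} for percent growth. All internal
#' computation is done on the unit scale; ingest and output rescale through
#' this object.
#'
#' @slot lo lower response bound.
#' @slot hi upper response bound.
#' @export
setClass("ResponseScale", representation(lo = "numeric", hi = "numeric"))

setValidity("ResponseScale", function(object) {
    if (length(object@lo) != 1L || length(object@hi) != 1L)
        return("lo and hi must be scalars")
    if (!is.finite(object@lo) || !is.finite(object@hi))
        return("bounds must be finite")
    if (object@lo >= object@hi) return("lo must be < hi")
    TRUE
})

#' @param lo,hi response bounds.
#' @rdname ResponseScale-class
#' @export
responseScale <- function(lo = 0, hi = 1) new("ResponseScale", lo = lo, hi = hi)

#' Monotherapy Hill curve
#'
#' Four-parameter Hill (log-logistic) dose-response curve for one
#' (cell line, drug) pair: response at zero dose, asymptotic response at
#' infinite dose, the half-effect concentration EC50 and the Hill slope.
#'
#' @slot e0 response at zero dose.
#' @slot emax asymptotic response at infinite dose.
#' @slot ec50 half-effect concentration (same units as the doses, e.g. uM).
#' @slot n Hill slope (> 0, dimensionless).
#' @slot degenerate flag set by [fitHill()] when the data were flat and the
#'   curve is a constant.
#' @seealso [hillResponse()], [fitHill()]
#' @export
setClass("HillCurve",
    representation(e0 = "numeric", emax = "numeric", ec50 = "numeric",
                   n = "numeric", degenerate = "logical"),
    prototype(degenerate = FALSE))

setValidity("HillCurve", function(object) {
    for (s in c("e0", "emax", "ec50", "n"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            return(sprintf("slot '%s' must be a finite scalar", s))
    if (object@ec50 <= 0) return("ec50 must be > 0")
    if (object@n <= 0) return("Hill slope n must be > 0")
    TRUE
})

#' @param e0,emax,ec50,n curve parameters, see slots.
#' @param degenerate flat-fit flag.
#' @rdname HillCurve-class
#' @export
HillCurve <- function(e0, emax, ec50, n, degenerate = FALSE)
    new("HillCurve", e0 = e0, emax = emax, ec50 = ec50, n = n,
        degenerate = degenerate)

#' BRAID combination response surface
#'
#' Parametric two-drug response surface in the BRAID (Bivariate Response to
#' Additive Interacting Doses) family: the two monotherapy Hill curves plus
#' an interaction pair (kappa, delta). kappa = 0, delta = 1 gives the
#' additive (Loewe-consistent) surface; kappa > 0 behaves synergy-like and
#' kappa < 0 antagonism-like. The BRAID domain requires kappa > -2.
#'
#' @slot hillA,hillB monotherapy [HillCurve-class] objects for the two drugs.
#' @slot kappa interaction strength (> -2; 0 = additive).
#' @slot delta second interaction parameter (> 0; 1 = neutral).
#' @slot degenerate flag set by [fitBraid()] when both monotherapies were flat.
#' @seealso [braidResponse()], [fitBraid()], [neutralSurface()]
#' @export
setClass("BraidSurface",
    representation(hillA = "HillCurve", hillB = "HillCurve",
                   kappa = "numeric", delta = "numeric", degenerate = "logical"),
    prototype(degenerate = FALSE))

setValidity("BraidSurface", function(object) {
    if (length(object@kappa) != 1L || !is.finite(object@kappa))
        return("kappa must be a finite scalar")
    if (object@kappa <= -2) return("kappa must be > -2 (BRAID domain)")
    if (length(object@delta) != 1L || !is.finite(object@delta) || object@delta <= 0)
        return("delta must be a finite scalar > 0")
    TRUE
})

#' @param hillA,hillB,kappa,delta,degenerate see slots.
#' @rdname BraidSurface-class
#' @export
BraidSurface <- function(hillA, hillB, kappa = 0, delta = 1, degenerate = FALSE)
    new("BraidSurface", hillA = hillA, hillB = hillB, kappa = kappa,
        delta = delta, degenerate = degenerate)

#' A measured (or predicted) response surface on a rectangular dose grid
#'
#' Holds the responses of one (cell line, drug A, drug B) triplet sampled on
#' the rectangular grid \code{dosesA x dosesB}; rows of \code{values} follow
#' \code{dosesA}. Missing grid cells are NA.
#'
#' @slot cell,drugA,drugB triplet identifiers.
#' @slot dosesA,dosesB strictly increasing concentrations (>= 0).
#' @slot values response matrix, \code{length(dosesA) x length(dosesB)}.
#' @slot scale the declared [ResponseScale-class].
#' @export
setClass("ResponseSurface",
    representation(cell = "character", drugA = "character", drugB = "character",
                   dosesA = "numeric", dosesB = "numeric", values = "matrix",
                   scale = "ResponseScale"))

setValidity("ResponseSurface", function(object) {
    if (any(object@dosesA < 0) || any(object@dosesB < 0))
        return("doses must be >= 0")
    if (is.unsorted(object@dosesA, strictly = TRUE) ||
        is.unsorted(object@dosesB, strictly = TRUE))
        return("doses must be strictly increasing")
    if (!all(dim(object@values) == c(length(object@dosesA), length(object@dosesB))))
        return("values shape must equal length(dosesA) x length(dosesB)")
    TRUE
})

#' @param cell,drugA,drugB,dosesA,dosesB,values,scale see slots.
#' @rdname ResponseSurface-class
#' @export
responseSurface <- function(cell, drugA, drugB, dosesA, dosesB, values,
                            scale = responseScale(0, 1))
    new("ResponseSurface", cell = as.character(cell), drugA = as.character(drugA),
        drugB = as.character(drugB), dosesA = dosesA, dosesB = dosesB,
        values = values, scale = scale)

#' Sampled Kronecker-product operator R (A x B) R^t
#'
#' Implicit symmetric PSD matrix whose (i, j) entry is
#' \code{factorA[rowsA[i], rowsA[j]] * factorB[rowsB[i], rowsB[j]]}: the
#' n x n submatrix of the Kronecker product \code{factorA \%x\% factorB}
#' selected by the sample index pairs, never materialised. Matrix-vector
#' products use the generalized vec trick (scatter, two dense products,
#' gather).
#'
#' @slot factorA,factorB symmetric PSD kernel matrices.
#' @slot rowsA,rowsB length-n index vectors into the two factors.
#' @seealso [kronMatvec()], [buildInputOperator()], [solveKRR()]
#' @export
setClass("SampledKronOperator",
    representation(factorA = "matrix", factorB = "matrix",
                   rowsA = "integer", rowsB = "integer"))

setValidity("SampledKronOperator", function(object) {
    if (nrow(object@factorA) != ncol(object@factorA) ||
        nrow(object@factorB) != ncol(object@factorB))
        return("kernel factors must be square")
    if (length(object@rowsA) != length(object@rowsB))
        return("rowsA and rowsB must have equal length")
    if (any(object@rowsA < 1L) || any(object@rowsA > nrow(object@factorA)))
        return("rowsA index out of range")
    if (any(object@rowsB < 1L) || any(object@rowsB > nrow(object@factorB)))
        return("rowsB index out of range")
    TRUE
})

#' Landmark surfaces for the output-kernel approximation
#'
#' A deterministic set of normalized surface vectors (one row per landmark,
#' length 64: the canonical 8x8 grid) together with the BRAID parameters that
#' generated them and the target mode they live in.
#'
#' @slot vectors numeric matrix, one normalized surface per row.
#' @slot params list of generating [BraidSurface-class] objects.
#' @slot mode \code{"direct"} or \code{"difference"}.
#' @seealso [generateLandmarks()], [buildNystromMap()]
#' @export
setClass("LandmarkSet",
    representation(vectors = "matrix", params = "list", mode = "character"))

setValidity("LandmarkSet", function(object) {
    if (nrow(object@vectors) == 0L) return("at least one landmark required")
    if (length(object@params) != nrow(object@vectors))
        return("params must match vectors rows")
    if (!object@mode %in% c("direct", "difference"))
        return("mode must be 'direct' or 'difference'")
    TRUE
})

#' Nystrom-approximated output feature map
#'
#' Finite-dimensional approximation psi(y) = k(y, L) K(L, L)^{-1/2} of the
#' RBF output-kernel feature map, built from landmark surfaces with the
#' spectrum truncated at an eigenvalue threshold for numerical stability.
#' Embeddings have length \code{effectiveDim} (the retained rank).
#'
#' @slot landmarks the [LandmarkSet-class].
#' @slot sigma output kernel bandwidth.
#' @slot eigvals retained eigenvalues of K(L, L) (all >= threshold).
#' @slot eigvecs corresponding eigenvectors (n_L x effectiveDim).
#' @slot effectiveDim retained rank.
#' @slot threshold the eigenvalue cutoff used.
#' @seealso [buildNystromMap()], [embedSurface()]
#' @export
setClass("NystromMap",
    representation(landmarks = "LandmarkSet", sigma = "numeric",
                   eigvals = "numeric", eigvecs = "matrix",
                   effectiveDim = "integer", threshold = "numeric"))

setValidity("NystromMap", function(object) {
    if (object@effectiveDim < 1L) return("effectiveDim must be >= 1")
    if (object@effectiveDim > nrow(object@landmarks@vectors))
        return("effectiveDim cannot exceed the number of landmarks")
    if (length(object@eigvals) != object@effectiveDim ||
        ncol(object@eigvecs) != object@effectiveDim)
        return("retained spectrum dimensions inconsistent")
    if (object@sigma <= 0) return("sigma must be > 0")
    TRUE
})

#' Dual-coefficient kernel ridge regression model
#'
#' Result of the early-stopped conjugate-gradient solve of
#' \code{(Op + lambda I) C = targets}; one coefficient row per training
#' sample, one column per output embedding dimension. The iteration count is
#' the regularizer; lambda is a small conditioning constant.
#'
#' @slot coeffs n x m dual coefficient matrix.
#' @slot operator the [SampledKronOperator-class] used in training.
#' @slot lambda ridge constant (>= 0).
#' @slot iterations early-stopping iteration count.
#' @seealso [solveKRR()], [predictEmbedding()]
#' @export
setClass("KrrDualModel",
    representation(coeffs = "matrix", operator = "SampledKronOperator",
                   lambda = "numeric", iterations = "integer"))

setValidity("KrrDualModel", function(object) {
    if (nrow(object@coeffs) != length(object@operator@rowsA))
        return("coefficient rows must align with operator samples")
    if (object@iterations < 1L) return("iterations must be >= 1")
    if (object@lambda < 0) return("lambda must be >= 0")
    TRUE
})

#' Fitted surface-regression model
#'
#' End-to-end fitted model: per-(cell, drug) Hill curves, per-triplet BRAID
#' fits, the Nystrom output map, input kernels and the dual KRR coefficients;
#' everything needed to predict a response surface for a query triplet.
#' Created by [surfaceKR()].
#'
#' @slot config configuration list from [surfaceKRConfig()].
#' @slot scale dataset [ResponseScale-class].
#' @slot hills named list of [HillCurve-class], keys \code{"cell||drug"}.
#' @slot surfaces list of training [ResponseSurface-class] objects.
#' @slot braids list of fitted [BraidSurface-class] objects (same order).
#' @slot map the [NystromMap-class].
#' @slot krr the [KrrDualModel-class] (NULL in cell-by-cell scope).
#' @slot cellIds,drugIds entity vocabularies.
#' @slot cellFeatures,drugFeatures training feature matrices (rows = ids).
#' @slot kCell,kDrug training kernel matrices.
#' @slot cellSigma RBF bandwidth used for the cell kernel (NA for delta).
#' @slot triplets data.frame of symmetrized training sample indices.
#' @slot submodels per-cell-line models when \code{scope = "cell_by_cell"}.
#' @export
setClass("SurfaceKRModel",
    representation(config = "list", scale = "ResponseScale", hills = "list",
                   surfaces = "list", braids = "list", map = "ANY",
                   krr = "ANY", cellIds = "character", drugIds = "character",
                   cellFeatures = "matrix", drugFeatures = "matrix",
                   kCell = "matrix", kDrug = "matrix", cellSigma = "numeric",
                   triplets = "data.frame", submodels = "list"))
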