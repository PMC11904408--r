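#' Construct a sampled Kronecker-product operator
#'
#' @param factorA,factorB symmetric PSD kernel matrices.
#' @param rowsA,rowsB equal-length index vectors defining the sampled rows
#'   of the Kronecker product \code{factorA \%x\% factorB}.
#' @return a [SampledKronOperator-class].
#' @export
sampledKronOperator <- function(factorA, factorB, rowsA, rowsB)
    new("SampledKronOperator", factorA = as.matrix(factorA),
        factorB = as.matrix(factorB), rowsA = as.integer(rowsA),
        rowsB = as.integer(rowsB))

#' Generalized vec-trick matrix-vector product
#'
#' Computes \code{R (A x B) R^t c} without materialising the Kronecker
#' product: the coefficient vector is scattered into a b x a matrix M (with
#' duplicate sample pairs accumulated), the dense product \code{B M A^t} is
#' formed, and the sampled entries are gathered back. Cost
#' O(n + a b min(a, b)) instead of O((a b)^2).
#'
#' @param op a [SampledKronOperator-class] with n samples.
#' @param v length-n numeric vector.
#' @return length-n numeric vector equal to the dense product.
#' @export
kronMatvec <- function(op, v) {
    stopifnot(is(op, "SampledKronOperator"))
    n <- length(op@rowsA)
    if (length(v) != n) stop("coefficient vector length must equal the sample count")
    a <- nrow(op@factorA); b <- nrow(op@factorB)
    M <- as.matrix(Matrix::sparseMatrix(i = op@rowsB, j = op@rowsA, x = v,
                                        dims = c(b, a)))
    N <- op@factorB %*% M %*% op@factorA  # factors are symmetric
    N[cbind(op@rowsB, op@rowsA)]
}

#' Build the sampled input operator for (cell, drug, drug) triplets
#'
#' The input kernel over triplets is the sampled three-factor Kronecker
#' product \code{R (K_c x K_d x K_d) R^t}. The iterative solver handles
#' two-factor products, so one part is pre-expanded explicitly: the
#' cell-drug product when there are no more cells than drugs, otherwise the
#' drug-drug product, keeping the explicit factor as small as possible.
#'
#' @param kCell,kDrug symmetric PSD kernel matrices over cell lines / drugs.
#' @param triplets data.frame with integer columns \code{cell},
#'   \code{drugA}, \code{drugB} indexing the kernels.
#' @param memoryBudgetBytes cap on the explicit factor (default 2 GiB);
#'   exceeding it errors with advice to use cell-by-cell scope.
#' @return a [SampledKronOperator-class] whose matvec equals the sampled
#'   triple-Kronecker product.
#' @export
buildInputOperator <- function(kCell, kDrug, triplets,
                               memoryBudgetBytes = 2 * 1024^3) {
    nC <- nrow(kCell); nD <- nrow(kDrug)
    stopifnot(all(triplets$cell >= 1L), all(triplets$cell <= nC),
              all(triplets$drugA >= 1L), all(triplets$drugA <= nD),
              all(triplets$drugB >= 1L), all(triplets$drugB <= nD))
    if (nC <= nD) {
        m <- as.numeric(nC) * nD
        if (8 * m^2 > memoryBudgetBytes)
            stop("explicit cell-drug kernel factor exceeds the memory budget; ",
                 "consider scope = 'cell_by_cell'")
        sampledKronOperator(kCell %x% kDrug, kDrug,
                            rowsA = (triplets$cell - 1L) * nD + triplets$drugA,
                            rowsB = triplets$drugB)
    } else {
        m <- as.numeric(nD) * nD
        if (8 * m^2 > memoryBudgetBytes)
            stop("explicit drug-drug kernel factor exceeds the memory budget; ",
                 "consider scope = 'cell_by_cell'")
        sampledKronOperator(kDrug %x% kDrug, kCell,
                            rowsA = (triplets$drugA - 1L) * nD + triplets$drugB,
                            rowsB = triplets$cell)
    }
}

#' Early-stopped conjugate-gradient KRR solve
#'
#' Runs plain conjugate gradients on the SPD system
#' \code{(Op + lambda I) C = targets}, one right-hand side per output
#' embedding dimension, from a zero start. The iteration count is the
#' regularizer (a spectral filter from the zero start); \code{lambda} is a
#' small constant kept only for conditioning. Iterations stop early if the
#' residual is already at machine level. Fully deterministic.
#'
#' @param op a [SampledKronOperator-class].
#' @param targets n x m numeric matrix (n = operator samples).
#' @param lambda ridge constant (default 1e-6).
#' @param maxIter iteration count, >= 1.
#' @return a [KrrDualModel-class].
#' @export
solveKRR <- function(op, targets, lambda = 1e-6, maxIter = 10L) {
    targets <- as.matrix(targets)
    if (nrow(targets) != length(op@rowsA))
        stop("target row count must equal the operator sample count")
    if (any(!is.finite(targets))) stop("targets must be finite")
    maxIter <- as.integer(maxIter)
    stopifnot(maxIter >= 1L)
    n <- nrow(targets)
    coeffs <- matrix(0, n, ncol(targets))
    for (j in seq_len(ncol(targets))) {
        b <- targets[, j]
        x <- numeric(n); r <- b; p <- r
        rs <- sum(r * r)
        if (sqrt(rs) < 1e-14) next
        for (it in seq_len(maxIter)) {
            Ap <- kronMatvec(op, p) + lambda * p
            alpha <- rs / sum(p * Ap)
            x <- x + alpha * p
            r <- r - alpha * Ap
            rs2 <- sum(r * r)
            if (sqrt(rs2) < 1e-14) break
            p <- r + (rs2 / rs) * p
            rs <- rs2
        }
        coeffs[, j] <- x
    }
    new("KrrDualModel", coeffs = coeffs, operator = op, lambda = lambda,
        iterations = maxIter)
}

#' Predict output embeddings for test triplets
#'
#' \code{g(x) = k_x(x, X) C}: multiplies test kernel rows (computed against
#' the training samples with the same kernels and ordering) by the dual
#' coefficients.
#'
#' @param model a [KrrDualModel-class].
#' @param testRows \code{n_test x n} matrix of input-kernel rows.
#' @return \code{n_test x m} matrix of predicted embeddings.
#' @export
predictEmbedding <- function(model, testRows) {
    if (is.null(dim(testRows))) testRows <- matrix(testRows, nrow = 1)
    if (ncol(testRows) != nrow(model@coeffs))
        stop("test kernel rows must have one column per training sample")
    testRows %*% model@coeffs
}

#' Input-kernel rows between triplet sets
#'
#' Elementwise product of the cell and drug kernel entries:
#' \code{k((c, a, b), (c', a', b')) = kCell[c, c'] kDrug[a, a'] kDrug[b, b']}.
#' Cross-kernel matrices allow unseen test entities.
#'
#' @param kCellCross,kDrugCross (test x train) kernel matrices over cells /
#'   drugs.
#' @param testTriplets,trainTriplets data.frames with columns \code{cell},
#'   \code{drugA}, \code{drugB} indexing the respective axes.
#' @return \code{nrow(testTriplets) x nrow(trainTriplets)} matrix.
#' @export
tripletKernel <- function(kCellCross, kDrugCross, testTriplets, trainTriplets) {
    kCellCross[testTriplets$cell, trainTriplets$cell, drop = FALSE] *
        kDrugCross[testTriplets$drugA, trainTriplets$drugA, drop = FALSE] *
        kDrugCross[testTriplets$drugB, trainTriplets$drugB, drop = FALSE]
}
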