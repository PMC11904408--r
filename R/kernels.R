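#' Gaussian (RBF) kernel matrix
#'
#' \code{K[i, j] = exp(-||x_i - y_j||^2 / (2 sigma^2))}. Normalized
#' (\code{k(x, x) = 1}), as the output-kernel formulation requires.
#'
#' @param X,Y numeric matrices with samples in rows (vectors are treated as
#'   a single row). \code{Y} defaults to \code{X}.
#' @param sigma bandwidth, > 0; see [sigmaHeuristic()].
#' @return \code{nrow(X) x nrow(Y)} kernel matrix.
#' @export
rbfKernel <- function(X, Y = X, sigma) {
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
    stopifnot(ncol(X) == ncol(Y))
    if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
        stop("sigma must be a positive scalar")
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
    exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Bandwidth heuristic: mean pairwise distance
#'
#' The RBF bandwidth used throughout: the mean Euclidean distance over all
#' distinct unordered sample pairs.
#'
#' @param X numeric matrix, samples in rows (>= 2 rows).
#' @return positive scalar.
#' @export
sigmaHeuristic <- function(X) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    if (nrow(X) < 2L) stop("at least two samples are required")
    s <- mean(stats::dist(X))
    if (!is.finite(s) || s <= 0)
        stop("all samples identical: pairwise-distance bandwidth is zero")
    s
}

#' Tanimoto kernel on binary fingerprints
#'
#' \code{K[i, j] = |a AND b| / |a OR b|} for binary fingerprint rows; the
#' standard similarity for substructure fingerprints.
#'
#' @param A,B binary (0/1) matrices with fingerprints in rows; every row
#'   must have at least one on-bit. \code{B} defaults to \code{A}.
#' @return \code{nrow(A) x nrow(B)} kernel matrix.
#' @export
tanimotoKernel <- function(A, B = A) {
    if (is.null(dim(A))) A <- matrix(A, nrow = 1)
    if (is.null(dim(B))) B <- matrix(B, nrow = 1)
    stopifnot(ncol(A) == ncol(B))
    if (!all(A %in% c(0, 1)) || !all(B %in% c(0, 1)))
        stop("fingerprints must be binary")
    if (any(rowSums(A) == 0) || any(rowSums(B) == 0))
        stop("all-zero fingerprint: Tanimoto similarity is undefined")
    inter <- tcrossprod(A, B)
    union <- outer(rowSums(A), rowSums(B), "+") - inter
    inter / union
}

#' Delta (identity) kernel on ids
#'
#' \code{K[i, j] = 1} when the ids match, else 0; the kernel induced by
#' one-hot identity features, used for cell lines when no continuous
#' features are available.
#'
#' @param idsA,idsB character vectors of entity ids.
#' @return \code{length(idsA) x length(idsB)} 0/1 matrix.
#' @export
deltaKernel <- function(idsA, idsB = idsA)
    outer(as.character(idsA), as.character(idsB), "==") * 1
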