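test_that("sampled Kronecker matvec equals the dense product", {
    set.seed(401)
    for (i in 1:50) {
        a <- sample(2:6, 1); b <- sample(2:7, 1); n <- sample(2:30, 1)
        A <- randPSD(a); B <- randPSD(b)
        rowsA <- sample(a, n, replace = TRUE); rowsB <- sample(b, n, replace = TRUE)
        op <- sampledKronOperator(A, B, rowsA, rowsB)
        dense <- denseSampledKron(A, B, rowsA, rowsB)
        v <- rnorm(n)
        expect_lt(max(abs(kronMatvec(op, v) - dense %*% v)), 1e-10)
    }
})

test_that("identity factors and scalar samplings behave trivially", {
    set.seed(402)
    # distinct pairs under identity factors: the operator is the identity
    pairs <- expand.grid(a = 1:3, b = 1:4)[sample(12, 6), ]
    op <- sampledKronOperator(diag(3), diag(4), pairs$a, pairs$b)
    v <- rnorm(6)
    expect_equal(kronMatvec(op, v), v)

    A <- randPSD(3); B <- randPSD(4)
    op1 <- sampledKronOperator(A, B, 2L, 3L)
    expect_equal(kronMatvec(op1, 5), A[2, 2] * B[3, 3] * 5)
    expect_error(sampledKronOperator(A, B, 4L, 1L), "out of range")
    expect_error(kronMatvec(op1, c(1, 2)), "length")
})

test_that("operator is symmetric and PSD when its factors are", {
    set.seed(403)
    A <- randPSD(5); B <- randPSD(6)
    rowsA <- sample(5, 20, TRUE); rowsB <- sample(6, 20, TRUE)
    op <- sampledKronOperator(A, B, rowsA, rowsB)
    for (i in 1:20) {
        u <- rnorm(20); v <- rnorm(20)
        expect_lt(abs(sum(u * kronMatvec(op, v)) - sum(v * kronMatvec(op, u))),
                  1e-10)
        expect_gt(sum(v * kronMatvec(op, v)), -1e-10)
    }
})

test_that("triplet input operator equals the sampled triple Kronecker product", {
    set.seed(404)
    kC <- randPSD(2); kD <- randPSD(3)
    trip <- data.frame(cell = c(1, 1, 2, 2, 1), drugA = c(1, 2, 3, 1, 3),
                       drugB = c(2, 3, 1, 2, 1))
    op <- buildInputOperator(kC, kD, trip)
    dense <- denseTripleKron(kC, kD, trip)
    for (i in 1:10) {
        v <- rnorm(5)
        expect_lt(max(abs(kronMatvec(op, v) - dense %*% v)), 1e-10)
    }
    # more cells than drugs: the other pre-expansion branch, same operator
    kC5 <- randPSD(5); kD2 <- randPSD(2)
    trip2 <- data.frame(cell = c(1, 3, 5, 2), drugA = c(1, 2, 1, 2),
                        drugB = c(2, 1, 2, 1))
    op2 <- buildInputOperator(kC5, kD2, trip2)
    dense2 <- denseTripleKron(kC5, kD2, trip2)
    v <- rnorm(4)
    expect_lt(max(abs(kronMatvec(op2, v) - dense2 %*% v)), 1e-10)
    expect_error(buildInputOperator(kC, kD, trip, memoryBudgetBytes = 10),
                 "cell_by_cell")
})

test_that("single-cell data reduces to the drug-pair operator", {
    set.seed(405)
    kD <- randPSD(4)
    trip <- data.frame(cell = rep(1L, 6), drugA = c(1, 2, 3, 4, 1, 2),
                       drugB = c(2, 3, 4, 1, 3, 4))
    op <- buildInputOperator(matrix(1), kD, trip)
    dense <- denseSampledKron(kD, kD, trip$drugA, trip$drugB)
    v <- rnorm(6)
    expect_lt(max(abs(kronMatvec(op, v) - dense %*% v)), 1e-10)
})

test_that("swapping every drug pair leaves the operator spectrum unchanged", {
    set.seed(406)
    kC <- randPSD(2); kD <- randPSD(4)
    trip <- data.frame(cell = sample(2, 8, TRUE), drugA = sample(4, 8, TRUE),
                       drugB = sample(4, 8, TRUE))
    swapped <- data.frame(cell = trip$cell, drugA = trip$drugB,
                          drugB = trip$drugA)
    ev1 <- eigen(denseTripleKron(kC, kD, trip), only.values = TRUE)$values
    ev2 <- eigen(denseTripleKron(kC, kD, swapped), only.values = TRUE)$values
    expect_equal(sort(ev1), sort(ev2), tolerance = 1e-9)
})

test_that("CG solve matches the dense solve and is linear in the targets", {
    set.seed(407)
    A <- randPSD(4); B <- randPSD(5)
    rowsA <- sample(4, 12, TRUE); rowsB <- sample(5, 12, TRUE)
    op <- sampledKronOperator(A, B, rowsA, rowsB)
    dense <- denseSampledKron(A, B, rowsA, rowsB)
    y <- matrix(rnorm(24), 12)
    fit <- solveKRR(op, y, lambda = 1e-6, maxIter = 500)
    ref <- solve(dense + 1e-6 * diag(12), y)
    expect_lt(max(abs(fit@coeffs - ref)) / max(abs(ref)), 1e-6)

    expect_equal(solveKRR(op, matrix(0, 12, 2), maxIter = 10)@coeffs,
                 matrix(0, 12, 2))
    joint <- solveKRR(op, y, maxIter = 7)@coeffs
    expect_equal(joint[, 1], drop(solveKRR(op, y[, 1, drop = FALSE],
                                           maxIter = 7)@coeffs))
    expect_error(solveKRR(op, matrix(NaN, 12, 1)), "finite")
})

test_that("CG error shrinks monotonically and early stopping traces a path", {
    set.seed(408)
    A <- randPSD(5); B <- randPSD(5)
    rowsA <- sample(5, 15, TRUE); rowsB <- sample(5, 15, TRUE)
    op <- sampledKronOperator(A, B, rowsA, rowsB)
    dense <- denseSampledKron(A, B, rowsA, rowsB) + 1e-6 * diag(15)
    y <- rnorm(15)
    xstar <- solve(dense, y)
    errA <- c(); res <- c()
    for (k in 1:12) {
        xk <- drop(solveKRR(op, matrix(y), lambda = 1e-6, maxIter = k)@coeffs)
        e <- xstar - xk
        errA <- c(errA, sqrt(sum(e * (dense %*% e))))
        res <- c(res, sqrt(sum((y - dense %*% xk)^2)))
    }
    # the A-norm of the error is guaranteed non-increasing for CG
    expect_true(all(diff(errA) <= 1e-8))
    # the training residual traces a decreasing early-stopping path overall
    # (per-step 2-norm monotonicity is not a CG guarantee)
    expect_lt(res[length(res)], 1e-3 * res[1])
})

test_that("embedding prediction interpolates, nulls and duplicates correctly", {
    set.seed(409)
    A <- randPSD(4); B <- randPSD(4)
    # distinct sample pairs: full-rank operator
    pairs <- expand.grid(a = 1:4, b = 1:4)[sample(16, 10), ]
    op <- sampledKronOperator(A, B, pairs$a, pairs$b)
    targets <- matrix(rnorm(20), 10)
    fit <- solveKRR(op, targets, lambda = 1e-9, maxIter = 500)
    dense <- denseSampledKron(A, B, pairs$a, pairs$b)
    pred <- predictEmbedding(fit, dense[3, ])  # a training row
    expect_lt(max(abs(pred - targets[3, ])) / max(abs(targets[3, ])), 1e-3)
    expect_equal(drop(predictEmbedding(fit, rep(0, 10))), c(0, 0))
    two <- predictEmbedding(fit, rbind(dense[3, ], dense[3, ]))
    expect_equal(two[1, ], two[2, ])
    expect_error(predictEmbedding(fit, rep(1, 9)), "column")
})
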