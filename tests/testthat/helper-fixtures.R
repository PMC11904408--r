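# Shared fixtures and independent oracles, built in code.

# random monotherapy curve; shared baseline e0 = 1 unless overridden
randHill <- function(e0 = 1) {
    HillCurve(e0 = e0, emax = runif(1, 0, 0.6), ec50 = 10^runif(1, -1, 0.5),
              n = runif(1, 0.6, 2.5))
}

# dense brute-force oracle for the sampled Kronecker operator
denseSampledKron <- function(A, B, rowsA, rowsB) {
    full <- A %x% B
    idx <- (rowsA - 1L) * nrow(B) + rowsB
    full[idx, idx, drop = FALSE]
}

# dense brute-force oracle for the sampled three-factor product
denseTripleKron <- function(kCell, kDrug, triplets) {
    nD <- nrow(kDrug)
    full <- kCell %x% kDrug %x% kDrug
    idx <- (triplets$cell - 1L) * nD * nD + (triplets$drugA - 1L) * nD +
        triplets$drugB
    full[idx, idx, drop = FALSE]
}

randPSD <- function(n) crossprod(matrix(rnorm(n * (n + 2)), n + 2, n)) / n

# triplet index table of a surface list
surfaceIndex <- function(surfaces) {
    data.frame(cell = vapply(surfaces, function(s) s@cell, character(1)),
               drugA = vapply(surfaces, function(s) s@drugA, character(1)),
               drugB = vapply(surfaces, function(s) s@drugB, character(1)))
}

# restrict a simulated long table to monotherapy rows plus the given surfaces
trainTableFor <- function(sim, trip, trainIdx) {
    keyAll <- paste(sim$table$cell_id, sim$table$drug_a, sim$table$drug_b)
    keyTr <- paste(trip$cell, trip$drugA, trip$drugB)[trainIdx]
    isMono <- sim$table$conc_a == 0 | sim$table$conc_b == 0
    sim$table[isMono | keyAll %in% keyTr, , drop = FALSE]
}

# pooled Pearson of predictions vs measured values over a surface subset
pooledPearson <- function(preds, surfaces) {
    p <- c(); y <- c()
    for (i in seq_along(surfaces)) {
        ok <- is.finite(surfaces[[i]]@values)
        p <- c(p, preds[[i]]$surface@values[ok])
        y <- c(y, surfaces[[i]]@values[ok])
    }
    cor(p, y)
}
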