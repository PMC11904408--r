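test_that("BRAID surface reduces to the monotherapy Hill curves on its axes", {
    set.seed(201)
    d <- c(0, 10^seq(-2, 1.5, length.out = 8))
    for (i in 1:25) {
        hA <- randHill(); hB <- randHill()
        bs <- BraidSurface(hA, hB, kappa = runif(1, -1.5, 4),
                           delta = 10^runif(1, -0.3, 0.3))
        expect_lt(max(abs(braidResponse(bs, d, 0) - hillResponse(hA, d))), 1e-10)
        expect_lt(max(abs(braidResponse(bs, 0, d) - hillResponse(hB, d))), 1e-10)
        expect_equal(braidResponse(bs, 0, 0), hA@e0)
    }
})

test_that("sham combination of a drug with itself is Loewe-additive", {
    set.seed(202)
    d <- 10^seq(-2, 1, length.out = 9)
    for (i in 1:10) {
        h <- randHill()
        sham <- BraidSurface(h, h, kappa = 0, delta = 1)
        for (al in c(0, 0.25, 0.5, 1))
            expect_lt(max(abs(braidResponse(sham, al * d, (1 - al) * d) -
                              hillResponse(h, d))), 1e-8)
    }
})

test_that("BRAID parameter domain is enforced", {
    h <- randHill()
    expect_error(BraidSurface(h, h, kappa = -2), "kappa")
    expect_error(BraidSurface(h, h, kappa = 0, delta = 0), "delta")
    expect_error(braidResponse(BraidSurface(h, h, 1, 1), -0.1, 1), "doses")
})

test_that("interaction fit recovers kappa from noiseless surfaces", {
    set.seed(203)
    # 4x4 grids across the antagonism-to-synergy range
    for (k in c(-1.5, -0.6, 0.5, 1, 2.5, 5)) {
        hA <- randHill(); hB <- randHill()
        truth <- BraidSurface(hA, hB, kappa = k, delta = 1)
        da <- hA@ec50 * c(1/8, 1/2, 2, 8); db <- hB@ec50 * c(1/8, 1/2, 2, 8)
        surf <- responseSurface("c", "a", "b", da, db, braidGrid(truth, da, db))
        fit <- fitBraid(surf, hA, hB)
        expect_lt(abs(fit@kappa - k) / abs(k), 0.05)
    }
    # neutral surface recovers kappa ~ 0
    hA <- randHill(); hB <- randHill()
    da <- hA@ec50 * c(1/8, 1/2, 2, 8); db <- hB@ec50 * c(1/8, 1/2, 2, 8)
    surf <- responseSurface("c", "a", "b", da, db,
                            braidGrid(BraidSurface(hA, hB, 0, 1), da, db))
    expect_lt(abs(fitBraid(surf, hA, hB)@kappa), 0.05)
})

test_that("interaction fit works on an anchored 7x2 grid", {
    set.seed(204)
    for (i in 1:5) {
        hA <- randHill(); hB <- randHill()
        truth <- BraidSurface(hA, hB, kappa = -1, delta = 1)
        da <- hA@ec50 * exp(seq(log(1/16), log(16), length.out = 7))
        db <- hB@ec50 * c(1/2, 2)
        surf <- responseSurface("c", "a", "b", da, db, braidGrid(truth, da, db))
        expect_lt(abs(fitBraid(surf, hA, hB)@kappa + 1), 0.15)
    }
})

test_that("degenerate monotherapy yields the flagged neutral fit", {
    flat <- HillCurve(0.5, 0.5, 1, 1, degenerate = TRUE)
    d <- c(0.1, 0.5, 2, 8)
    surf <- responseSurface("c", "a", "b", d, d, matrix(0.5, 4, 4))
    fit <- fitBraid(surf, flat, flat)
    expect_true(fit@degenerate)
    expect_equal(fit@kappa, 0)
    expect_equal(fit@delta, 1)
})

test_that("difference surface plus neutral restores the full surface exactly", {
    set.seed(205)
    for (i in 1:10) {
        hA <- randHill(); hB <- randHill()
        bs <- BraidSurface(hA, hB, kappa = runif(1, -1.5, 4), delta = 1)
        d1 <- 10^runif(20, -2, 1.5); d2 <- 10^runif(20, -2, 1.5)
        full <- differenceResponse(bs, d1, d2) +
            braidResponse(neutralSurface(hA, hB), d1, d2)
        expect_lt(max(abs(full - braidResponse(bs, d1, d2))), 1e-12)
        # kappa = 0 means an identically zero difference
        neu <- BraidSurface(hA, hB, 0, 1)
        expect_lt(max(abs(differenceResponse(neu, d1, d2))), 1e-12)
    }
})

test_that("synergy lowers growth below the additive surface", {
    set.seed(206)
    for (i in 1:10) {
        hA <- randHill(); hB <- randHill()
        bs <- BraidSurface(hA, hB, kappa = runif(1, 0.5, 4), delta = 1)
        d1 <- hA@ec50 * 10^runif(25, -1, 1)
        d2 <- hB@ec50 * 10^runif(25, -1, 1)
        # growth scale: responses decrease with effect, so delta <= 0
        expect_true(all(differenceResponse(bs, d1, d2) <= 1e-12))
    }
})

test_that("surface normalization is symmetric, midpoint-flat and injective", {
    h <- HillCurve(1, 0.2, 0.7, 1.6)
    v <- normalizeSurface(neutralSurface(h, h), "direct")
    m <- matrix(v, 8, 8, byrow = TRUE)
    expect_equal(m, t(m), tolerance = 1e-12)   # identical drugs: transposable
    expect_length(v, 64)

    flat <- HillCurve(0.5, 0.5, 1, 1, degenerate = TRUE)
    expect_equal(normalizeSurface(neutralSurface(flat, flat), "direct"),
                 rep(0.5, 64))

    hB <- HillCurve(1, 0.3, 1.1, 1.2)
    v1 <- normalizeSurface(BraidSurface(h, hB, 0.5, 1), "direct")
    v2 <- normalizeSurface(BraidSurface(h, hB, 2.0, 1), "direct")
    expect_gt(sqrt(sum((v1 - v2)^2)), 0)
})
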