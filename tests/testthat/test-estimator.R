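test_that("configurations span the ablation grid and validate", {
    expect_equal(ablationConfig("GD-Diff")[c("mode", "solver")],
                 list(mode = "difference", solver = "pgd"))
    expect_equal(ablationConfig("C-Dir")[c("mode", "solver")],
                 list(mode = "direct", solver = "candidate"))
    expect_error(surfaceKRConfig(maxIter = 0), "maxIter")
    expect_error(ablationConfig("X-Diff"))
})

test_that("the fitted model beats the no-learning baseline on its training set", {
    sim <- simulateComboData(nCells = 4, nDrugs = 6, noiseSd = 0.05, seed = 31)
    loaded <- loadResponseTable(sim$table, sim$scale)
    model <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                       ablationConfig("C-Diff"), sim$scale)
    expect_s4_class(model, "SurfaceKRModel")
    sub <- loaded$surfaces[seq(1, length(loaded$surfaces), by = 2)]
    preds <- predictForSurfaces(model, sub)
    base <- lapply(sub, function(s)
        neutralBaseline(model, s@cell, s@drugA, s@drugB, s@dosesA, s@dosesB))
    evP <- evaluatePredictions(lapply(preds, `[[`, "surface"), sub)
    evB <- evaluatePredictions(lapply(base, `[[`, "surface"), sub)
    expect_lt(evP$rmseMean, evB$rmseMean)
    expect_gt(evP$pearson, evB$pearson)
})

test_that("with all-additive data the learner returns the neutral baseline", {
    sim <- simulateComboData(nCells = 3, nDrugs = 5, noiseSd = 0,
                             kappaModel = "zero", seed = 37)
    loaded <- loadResponseTable(sim$table, sim$scale)
    model <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                       ablationConfig("C-Diff"), sim$scale)
    for (s in loaded$surfaces[1:10]) {
        p <- predictSurface(model, s@cell, s@drugA, s@drugB, s@dosesA,
                            s@dosesB)
        b <- neutralBaseline(model, s@cell, s@drugA, s@drugB, s@dosesA,
                             s@dosesB)
        expect_lt(sqrt(mean((p$surface@values - b$surface@values)^2)), 0.02)
        expect_lt(abs(p$params@kappa), 0.3)
    }
})

test_that("predictions are equivariant to the drug ordering", {
    sim <- simulateComboData(nCells = 3, nDrugs = 5, noiseSd = 0.05, seed = 41)
    loaded <- loadResponseTable(sim$table, sim$scale)
    s <- loaded$surfaces[[5]]
    for (variant in c("C-Diff", "GD-Diff")) {
        model <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                           ablationConfig(variant), sim$scale)
        fwd <- predictSurface(model, s@cell, s@drugA, s@drugB, s@dosesA,
                              s@dosesB)
        rev <- predictSurface(model, s@cell, s@drugB, s@drugA, s@dosesB,
                              s@dosesA)
        expect_equal(fwd$surface@values, t(rev$surface@values),
                     tolerance = 1e-8)
    }
})

test_that("an interpolating configuration memorizes its training surfaces", {
    set.seed(43)
    # noiseless data whose interactions sit on the candidate grid
    sim <- simulateComboData(nCells = 3, nDrugs = 5, noiseSd = 0,
                             kappaModel = "zero", seed = 43)
    kOptions <- c(-1, 0, 1.5, 3)
    kap <- sim$truth$kappa
    tab <- sim$table[sim$table$conc_a == 0 | sim$table$conc_b == 0, ]
    hills <- sim$truth$hills
    rows <- list(tab)
    for (i in seq_len(nrow(kap))) {
        hA <- with(hills[hills$cell == kap$cell[i] &
                         hills$drug == kap$drugA[i], ],
                   HillCurve(e0, emax, ec50, n))
        hB <- with(hills[hills$cell == kap$cell[i] &
                         hills$drug == kap$drugB[i], ],
                   HillCurve(e0, emax, ec50, n))
        k <- sample(kOptions, 1)
        d1 <- hA@ec50 * c(1/8, 1/2, 2, 8); d2 <- hB@ec50 * c(1/8, 1/2, 2, 8)
        g <- expand.grid(conc_a = d1, conc_b = d2)
        rows[[i + 1]] <- data.frame(
            cell_id = kap$cell[i], drug_a = kap$drugA[i],
            drug_b = kap$drugB[i], conc_a = g$conc_a, conc_b = g$conc_b,
            response = pmin(pmax(braidResponse(
                BraidSurface(hA, hB, k, 1), g$conc_a, g$conc_b), 0), 1))
    }
    tab <- do.call(rbind, rows)

    # landmarks = the training outputs themselves, full spectrum, tiny ridge
    prepModel <- surfaceKR(tab, sim$cellFeatures, sim$drugFingerprints,
                           ablationConfig("C-Diff", maxIter = 3), sim$scale)
    vecs <- t(vapply(prepModel@braids, normalizeSurface, numeric(64),
                     mode = "difference"))
    lms <- new("LandmarkSet", vectors = unique(vecs),
               params = prepModel@braids[!duplicated(vecs)],
               mode = "difference")
    cfg <- ablationConfig("C-Diff", maxIter = 400, lambda = 1e-9,
                          eigThreshold = 1e-8, landmarkSet = lms,
                          kappaGrid = kOptions, deltaGrid = 1)
    model <- surfaceKR(tab, sim$cellFeatures, sim$drugFingerprints, cfg,
                       sim$scale)
    idx <- seq(1, length(model@surfaces), by = 3)
    for (i in idx) {
        s <- model@surfaces[[i]]
        fitVals <- braidGrid(model@braids[[i]], s@dosesA, s@dosesB)
        p <- predictSurface(model, s@cell, s@drugA, s@drugB, s@dosesA,
                            s@dosesB)
        expect_lt(sqrt(mean((p$surface@values - fitVals)^2)), 0.02)
    }
})

test_that("cell-by-cell scope equals the full scope on single-cell data", {
    sim <- simulateComboData(nCells = 1, nDrugs = 5, noiseSd = 0.05, seed = 47)
    loaded <- loadResponseTable(sim$table, sim$scale)
    full <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                      ablationConfig("C-Diff", cellKernel = "delta"),
                      sim$scale)
    cbc <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                     ablationConfig("C-Diff", cellKernel = "delta",
                                    scope = "cell_by_cell"), sim$scale)
    for (s in loaded$surfaces[1:5]) {
        pF <- predictSurface(full, s@cell, s@drugA, s@drugB, s@dosesA,
                             s@dosesB)
        pC <- predictSurface(cbc, s@cell, s@drugA, s@drugB, s@dosesA,
                             s@dosesB)
        expect_equal(pF$surface@values, pC$surface@values, tolerance = 1e-10)
    }
})

test_that("unseen entities demand features, naming the scenario", {
    sim <- simulateComboData(nCells = 2, nDrugs = 4, seed = 53)
    model <- surfaceKR(sim$table, sim$cellFeatures, sim$drugFingerprints,
                       ablationConfig("C-Diff", maxIter = 3), sim$scale)
    expect_error(predictSurface(model, "cellXX", "drug01", "drug02", 1:2, 1:2),
                 "new-cell-line")
    expect_error(predictSurface(model, "cell01", "drugXX", "drug02", 1:2, 1:2),
                 "new-drug")
})

test_that("cross-validation of the stopping iteration is deterministic", {
    sim <- simulateComboData(nCells = 3, nDrugs = 5, noiseSd = 0.05, seed = 59)
    cfg <- ablationConfig("C-Diff")
    one <- crossValidate(sim$table, sim$cellFeatures, sim$drugFingerprints,
                         cfg, nFolds = 2, maxIterGrid = 7, seed = 3)
    expect_equal(one$best$maxIter, 7L)   # single candidate returned untouched

    cv1 <- crossValidate(sim$table, sim$cellFeatures, sim$drugFingerprints,
                         cfg, nFolds = 2, maxIterGrid = c(3, 10), seed = 3)
    cv2 <- crossValidate(sim$table, sim$cellFeatures, sim$drugFingerprints,
                         cfg, nFolds = 2, maxIterGrid = c(3, 10), seed = 3)
    expect_identical(cv1$best$maxIter, cv2$best$maxIter)
    expect_equal(cv1$results$pearson, cv2$results$pearson)
    expect_true(all(is.finite(cv1$results$pearson)))
})
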