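test_that("long tables are validated, collapsed and routed", {
    tab <- data.frame(cell_id = "c1", drug_a = "d1", drug_b = "d2",
                      conc_a = 1, conc_b = 2,
                      response = c(0.4, 0.5, 0.6, 0.9))
    out <- loadResponseTable(tab, minComboCells = 1L)
    expect_equal(nrow(out$table), 1L)
    expect_equal(out$table$response, 0.55)  # median over replicates

    monoOnly <- data.frame(cell_id = "c1", drug_a = "d1", drug_b = "",
                           conc_a = c(0.1, 1, 10), conc_b = 0,
                           response = c(0.9, 0.5, 0.2))
    expect_message(res <- loadResponseTable(monoOnly), "monotherapy-only")
    expect_length(res$surfaces, 0)
    expect_equal(nrow(res$monotherapy), 3L)

    expect_error(loadResponseTable(tab[, -6]), "missing required columns")
    bad <- tab; bad$conc_a <- "x"
    expect_error(loadResponseTable(bad), "non-numeric")
})

test_that("combination rows assemble into surfaces with full grids", {
    set.seed(801)
    d <- c(0.1, 0.5, 2, 8)
    g <- expand.grid(conc_a = d, conc_b = d)
    tab <- rbind(
        data.frame(cell_id = "c1", drug_a = "d1", drug_b = "d2",
                   conc_a = g$conc_a, conc_b = g$conc_b,
                   response = runif(16)),
        data.frame(cell_id = "c2", drug_a = "d1", drug_b = "d3",
                   conc_a = g$conc_a, conc_b = g$conc_b,
                   response = runif(16)))
    out <- loadResponseTable(tab)
    expect_length(out$surfaces, 2)
    expect_true(all(vapply(out$surfaces,
                           function(s) sum(is.finite(s@values)) == 16L,
                           logical(1))))
})

test_that("fitted surface parameters survive a CSV round trip", {
    set.seed(802)
    hA <- randHill(); hB <- randHill()
    d <- c(0.1, 0.5, 2, 8)
    surf <- responseSurface("c1", "d1", "d2", d, d,
                            braidGrid(BraidSurface(hA, hB, 1.5, 1), d, d))
    fit <- fitBraid(surf, hA, hB)
    path <- tempfile(fileext = ".csv")
    writeBraidFits(list(surf), list(fit), path)
    back <- readBraidFits(path)
    expect_equal(back$kappa, fit@kappa, tolerance = 1e-10)
    expect_equal(back$cell, "c1")
})

test_that("combinatorial coverage matches the screens' printed statistics", {
    expect_equal(datasetStats(125, 64, 68982)$percent, 27.4)
    expect_equal(datasetStats(60, 104, 311527)$percent, 96.9)
    expect_equal(datasetStats(39, 38, 22527)$percent, 82.2)
    expect_equal(datasetStats(1, 2, 1)$percent, 100.0)
    expect_error(datasetStats(1, 2, 5), "more surfaces")
})

test_that("MACCS fingerprints come out as 166 binary keys", {
    fps <- fingerprintsFromSmiles(c("c1ccccc1", "CCO", "c1ccccc1"),
                                  ids = c("benzene", "ethanol", "benzene2"))
    expect_equal(ncol(fps), 166L)
    expect_true(all(fps %in% c(0L, 1L)))
    expect_true(all(rowSums(fps) >= 1))
    # duplicate SMILES: identical fingerprints, Tanimoto similarity 1
    expect_equal(drop(tanimotoKernel(fps["benzene", ], fps["benzene2", ])), 1)
    expect_warning(out <- fingerprintsFromSmiles(c("CCO", "xyz]q")),
                   "dropping")
    expect_equal(nrow(out), 1L)
})

test_that("splits respect their scenario constraints across seeds", {
    cells <- sprintf("c%d", 1:5); drugs <- sprintf("d%d", 1:8)
    pairs <- t(combn(drugs, 2))
    trip <- do.call(rbind, lapply(cells, function(cl)
        data.frame(cell = cl, drugA = pairs[, 1], drugB = pairs[, 2])))
    for (seed in 1:20) {
        for (sc in c("new_combo", "new_drug", "new_cell_line")) {
            sp <- makeSplits(trip, sc, nSplits = 3, seed = seed)
            expect_true(auditSplits(sp, trip))
        }
    }
    # new_combo folds partition the surfaces
    sp <- makeSplits(trip, "new_combo", nSplits = 4, seed = 3)
    allTest <- sort(unlist(lapply(sp$folds, `[[`, "test")))
    expect_equal(allTest, seq_len(nrow(trip)))
    # new_cell_line: test cells disjoint from training cells
    sp <- makeSplits(trip, "new_cell_line", nSplits = 5, seed = 4)
    for (f in sp$folds)
        expect_length(intersect(trip$cell[f$train], trip$cell[f$test]), 0)
    # new_drug: every test surface has exactly one unseen (cell, drug) pair
    sp <- makeSplits(trip, "new_drug", nSplits = 3, seed = 5)
    for (f in sp$folds) {
        seen <- unique(c(paste(trip$cell[f$train], trip$drugA[f$train]),
                         paste(trip$cell[f$train], trip$drugB[f$train])))
        nSeen <- (paste(trip$cell[f$test], trip$drugA[f$test]) %in% seen) +
                 (paste(trip$cell[f$test], trip$drugB[f$test]) %in% seen)
        expect_true(all(nSeen <= 1))
    }
})
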