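#' Configuration for the surface-regression estimator
#'
#' The four (mode, solver) pairs form the ablation grid: difference or
#' direct surface target, candidate-set or projected-gradient pre-image
#' solver. Early stopping of the conjugate-gradient solver (\code{maxIter})
#' is the regularizer; \code{lambda} is a small conditioning constant only.
#'
#' @param mode regression target: \code{"difference"} (deviation from the
#'   additive surface; the default and usually the better choice) or
#'   \code{"direct"} (the full surface).
#' @param solver pre-image solver: \code{"pgd"} or \code{"candidate"}.
#' @param maxIter CG early-stopping iteration count (cross-validated over
#'   c(3, 5, 10) in [crossValidate()]).
#' @param lambda ridge constant. At large training sizes early stopping is
#'   the effective regularizer and lambda can be tiny; at a few hundred
#'   samples CG converges within the iteration budget, so a real ridge is
#'   needed — the default 0.1 sits mid-range of the standard grid
#'   (1e-2 to 5e-1) used for kernel ridge regression with normalized
#'   kernels.
#' @param eigThreshold Nystrom eigenvalue cutoff.
#' @param cellKernel \code{"rbf"} on continuous features or \code{"delta"}
#'   on identities.
#' @param drugKernel \code{"tanimoto"} on binary fingerprints or
#'   \code{"rbf"} on continuous features.
#' @param kappaGrid,deltaGrid candidate grids for the pre-image search.
#' @param landmarkKappa,landmarkDelta interaction grids for landmark
#'   generation.
#' @param archetypes Hill archetype pairs for landmarks.
#' @param landmarkSet optional pre-built [LandmarkSet-class] overriding the
#'   generated landmarks (its mode must match \code{mode}).
#' @param pgdSteps,pgdLr projected-gradient solver hyperparameters.
#' @param scope \code{"full"} (one model over all cell lines) or
#'   \code{"cell_by_cell"} (an independent model per cell line).
#' @param memoryBudgetBytes cap for the pre-expanded kernel factor.
#' @param minComboCells minimum measured combination cells per surface.
#' @return a named configuration list.
#' @export
surfaceKRConfig <- function(mode = c("difference", "direct"),
                            solver = c("pgd", "candidate"),
                            maxIter = 10L, lambda = 0.1, eigThreshold = 0.1,
                            cellKernel = c("rbf", "delta"),
                            drugKernel = c("tanimoto", "rbf"),
                            kappaGrid = kappaGridDefault(),
                            deltaGrid = 1,
                            landmarkKappa = c(-1.5, -0.5, 0, 0.5, 1.5, 3),
                            landmarkDelta = c(0.5, 1, 2),
                            archetypes = defaultArchetypes(),
                            landmarkSet = NULL,
                            pgdSteps = 200L, pgdLr = 0.05,
                            scope = c("full", "cell_by_cell"),
                            memoryBudgetBytes = 2 * 1024^3,
                            minComboCells = 4L) {
    cfg <- list(mode = match.arg(mode), solver = match.arg(solver),
                maxIter = as.integer(maxIter), lambda = lambda,
                eigThreshold = eigThreshold,
                cellKernel = match.arg(cellKernel),
                drugKernel = match.arg(drugKernel),
                kappaGrid = kappaGrid, deltaGrid = deltaGrid,
                landmarkKappa = landmarkKappa, landmarkDelta = landmarkDelta,
                archetypes = archetypes, landmarkSet = landmarkSet,
                pgdSteps = as.integer(pgdSteps), pgdLr = pgdLr,
                scope = match.arg(scope),
                memoryBudgetBytes = memoryBudgetBytes,
                minComboCells = as.integer(minComboCells))
    stopifnot(cfg$maxIter >= 1L)
    cfg
}

#' @rdname surfaceKRConfig
#' @param variant one of \code{"GD-Diff"}, \code{"GD-Dir"}, \code{"C-Diff"},
#'   \code{"C-Dir"} — the ablation grid shorthand.
#' @param ... further arguments passed to [surfaceKRConfig()].
#' @export
ablationConfig <- function(variant = c("GD-Diff", "GD-Dir", "C-Diff", "C-Dir"),
                           ...) {
    variant <- match.arg(variant)
    surfaceKRConfig(
        mode = if (grepl("Diff$", variant)) "difference" else "direct",
        solver = if (grepl("^GD", variant)) "pgd" else "candidate", ...)
}

.hillKey <- function(cell, drug) paste(cell, drug, sep = "\r")

# stage 1: ingest + per-entity fits shared by all configurations and folds
.prepareTraining <- function(x, cellFeatures, drugFeatures,
                             scale = responseScale(0, 1), minComboCells = 4L) {
    loaded <- if (is.list(x) && !is.data.frame(x) && !is.null(x$surfaces)) x
        else loadResponseTable(x, scale, minComboCells)
    cellIds <- rownames(cellFeatures); drugIds <- rownames(drugFeatures)
    if (is.null(cellIds) || is.null(drugIds))
        stop("feature matrices must have entity ids as rownames")

    mono <- loaded$monotherapy
    known <- mono$cell %in% cellIds & mono$drug %in% drugIds
    mono <- mono[known, , drop = FALSE]

    surfaces <- loaded$surfaces
    keep <- vapply(surfaces, function(s)
        s@cell %in% cellIds && s@drugA %in% drugIds && s@drugB %in% drugIds,
        logical(1))
    if (any(!keep))
        message(sprintf("dropping %d surfaces lacking cell or drug features",
                        sum(!keep)))
    surfaces <- surfaces[keep]

    # monotherapy Hill fit per (cell, drug), on the unit scale
    hills <- list()
    if (nrow(mono)) {
        unit <- (mono$response - scale@lo) / (scale@hi - scale@lo)
        key <- .hillKey(mono$cell, mono$drug)
        for (k in unique(key)) {
            sel <- key == k
            h <- try(fitHill(mono$dose[sel], unit[sel]), silent = TRUE)
            if (!inherits(h, "try-error")) hills[[k]] <- h
        }
    }

    fit <- vapply(surfaces, function(s)
        !is.null(hills[[.hillKey(s@cell, s@drugA)]]) &&
        !is.null(hills[[.hillKey(s@cell, s@drugB)]]), logical(1))
    if (any(!fit))
        message(sprintf("excluding %d surfaces with unfittable monotherapy",
                        sum(!fit)))
    surfaces <- surfaces[fit]
    if (length(surfaces) == 0L) stop("no fittable training surfaces")

    braids <- lapply(surfaces, function(s)
        fitBraid(s, hills[[.hillKey(s@cell, s@drugA)]],
                 hills[[.hillKey(s@cell, s@drugB)]]))

    list(scale = scale, surfaces = surfaces, braids = braids, hills = hills,
         cellFeatures = as.matrix(cellFeatures),
         drugFeatures = as.matrix(drugFeatures),
         cellIds = cellIds, drugIds = drugIds)
}

.cellKernelOf <- function(cfg, prep) {
    if (cfg$cellKernel == "delta")
        list(K = deltaKernel(prep$cellIds), sigma = NA_real_)
    else {
        s <- sigmaHeuristic(prep$cellFeatures)
        list(K = rbfKernel(prep$cellFeatures, sigma = s), sigma = s)
    }
}

.drugKernelOf <- function(cfg, prep) {
    if (cfg$drugKernel == "tanimoto") tanimotoKernel(prep$drugFeatures)
    else rbfKernel(prep$drugFeatures, sigma = sigmaHeuristic(prep$drugFeatures))
}

# stage 2: output map + symmetrized targets + operator + CG solve
.fitCore <- function(prep, cfg, trainIdx = seq_along(prep$surfaces)) {
    landmarks <- cfg$landmarkSet
    if (is.null(landmarks))
        landmarks <- generateLandmarks(cfg$archetypes, cfg$landmarkKappa,
                                       cfg$landmarkDelta, cfg$mode)
    if (landmarks@mode != cfg$mode)
        stop("landmark set mode does not match the configured mode")
    map <- buildNystromMap(landmarks, cfg$eigThreshold)

    surfaces <- prep$surfaces[trainIdx]
    braids <- prep$braids[trainIdx]

    # symmetrized training set: each surface under both drug orderings
    cellIdx <- integer(0); aIdx <- integer(0); bIdx <- integer(0)
    targets <- list()
    for (i in seq_along(surfaces)) {
        s <- surfaces[[i]]
        v <- normalizeSurface(braids[[i]], cfg$mode)
        ci <- match(s@cell, prep$cellIds)
        ai <- match(s@drugA, prep$drugIds); bi <- match(s@drugB, prep$drugIds)
        cellIdx <- c(cellIdx, ci); aIdx <- c(aIdx, ai); bIdx <- c(bIdx, bi)
        targets[[length(targets) + 1L]] <- v
        if (ai != bi) {
            cellIdx <- c(cellIdx, ci); aIdx <- c(aIdx, bi); bIdx <- c(bIdx, ai)
            targets[[length(targets) + 1L]] <- .transposeVec(v)
        }
    }
    triplets <- data.frame(cell = cellIdx, drugA = aIdx, drugB = bIdx)
    psi <- embedSurface(map, do.call(rbind, targets))

    cellK <- .cellKernelOf(cfg, prep)
    kDrug <- .drugKernelOf(cfg, prep)
    op <- buildInputOperator(cellK$K, kDrug, triplets,
                             memoryBudgetBytes = cfg$memoryBudgetBytes)
    krr <- solveKRR(op, psi, lambda = cfg$lambda, maxIter = cfg$maxIter)

    new("SurfaceKRModel", config = cfg, scale = prep$scale,
        hills = prep$hills, surfaces = surfaces, braids = braids,
        map = map, krr = krr, cellIds = prep$cellIds, drugIds = prep$drugIds,
        cellFeatures = prep$cellFeatures, drugFeatures = prep$drugFeatures,
        kCell = cellK$K, kDrug = kDrug, cellSigma = cellK$sigma,
        triplets = triplets, submodels = list())
}

#' Fit the surface-regression model
#'
#' End-to-end training: per-(cell, drug) Hill fits from the monotherapy
#' rows, per-triplet BRAID fits, landmark generation and the Nystrom output
#' map, mode-dependent normalized targets (full surface or deviation from
#' additivity), input kernels, the sampled-Kronecker operator and the
#' early-stopped CG solve. Training is symmetrized over both drug orderings
#' so that predictions are order-equivariant. Rows lacking features and
#' surfaces with unfittable monotherapy are dropped with a message.
#'
#' @param x long-format response table (path, data.frame, or the result of
#'   [loadResponseTable()]).
#' @param cellFeatures,drugFeatures feature matrices with entity ids as
#'   rownames (binary fingerprints for drugs under the Tanimoto kernel).
#' @param config a [surfaceKRConfig()] list.
#' @param scale dataset [ResponseScale-class].
#' @return a [SurfaceKRModel-class].
#' @seealso [predictSurface()], [neutralBaseline()], [crossValidate()]
#' @export
surfaceKR <- function(x, cellFeatures, drugFeatures,
                      config = surfaceKRConfig(),
                      scale = responseScale(0, 1)) {
    prep <- .prepareTraining(x, cellFeatures, drugFeatures, scale,
                             config$minComboCells)
    if (config$scope == "cell_by_cell") {
        cells <- unique(vapply(prep$surfaces, function(s) s@cell, character(1)))
        subs <- list()
        for (cl in cells) {
            idx <- which(vapply(prep$surfaces, function(s) s@cell == cl,
                                logical(1)))
            sub <- prep
            sub$cellFeatures <- prep$cellFeatures[cl, , drop = FALSE]
            sub$cellIds <- cl
            subCfg <- config; subCfg$scope <- "full"
            subCfg$cellKernel <- "delta"  # a single cell line: unit kernel
            subPrep <- sub
            subPrep$surfaces <- prep$surfaces[idx]
            subPrep$braids <- prep$braids[idx]
            subs[[cl]] <- .fitCore(subPrep, subCfg)
        }
        model <- new("SurfaceKRModel", config = config, scale = prep$scale,
                     hills = prep$hills, surfaces = prep$surfaces,
                     braids = prep$braids, map = NULL, krr = NULL,
                     cellIds = prep$cellIds, drugIds = prep$drugIds,
                     cellFeatures = prep$cellFeatures,
                     drugFeatures = prep$drugFeatures,
                     kCell = matrix(0, 0, 0), kDrug = matrix(0, 0, 0),
                     cellSigma = NA_real_,
                     triplets = data.frame(), submodels = subs)
        return(model)
    }
    .fitCore(prep, config)
}

# cross-kernel rows between one query triplet (both orderings) and training
.queryEmbeddings <- function(model, cell, drugA, drugB,
                             newCellFeatures = NULL, newDrugFeatures = NULL) {
    cfg <- model@config
    cellFeat <- function(id) {
        if (id %in% model@cellIds)
            model@cellFeatures[id, , drop = FALSE]
        else if (!is.null(newCellFeatures) && id %in% rownames(newCellFeatures))
            newCellFeatures[id, , drop = FALSE]
        else stop(sprintf(
            "cell line '%s' has no features: the new-cell-line scenario requires features, not history", id))
    }
    drugFeat <- function(id) {
        if (id %in% model@drugIds)
            model@drugFeatures[id, , drop = FALSE]
        else if (!is.null(newDrugFeatures) && id %in% rownames(newDrugFeatures))
            newDrugFeatures[id, , drop = FALSE]
        else stop(sprintf(
            "drug '%s' has no features: the new-drug scenario requires features, not history", id))
    }
    kCellRow <- if (cfg$cellKernel == "delta") {
        deltaKernel(cell, model@cellIds)
    } else {
        rbfKernel(cellFeat(cell), model@cellFeatures, sigma = model@cellSigma)
    }
    kD <- function(id) {
        if (cfg$drugKernel == "tanimoto")
            tanimotoKernel(drugFeat(id), model@drugFeatures)
        else rbfKernel(drugFeat(id), model@drugFeatures,
                       sigma = sigmaHeuristic(model@drugFeatures))
    }
    kA <- kD(drugA); kB <- kD(drugB)
    tr <- model@triplets
    rowFwd <- kCellRow[1, tr$cell] * kA[1, tr$drugA] * kB[1, tr$drugB]
    rowSwp <- kCellRow[1, tr$cell] * kB[1, tr$drugA] * kA[1, tr$drugB]
    list(g1 = drop(predictEmbedding(model@krr, rowFwd)),
         g2 = drop(predictEmbedding(model@krr, rowSwp)))
}

.queryHills <- function(model, cell, drugA, drugB) {
    hA <- model@hills[[.hillKey(cell, drugA)]]
    hB <- model@hills[[.hillKey(cell, drugB)]]
    if (is.null(hA) || is.null(hB))
        stop(sprintf("no monotherapy Hill fit for triplet (%s, %s, %s)",
                     cell, drugA, drugB))
    list(a = hA, b = hB)
}

#' Predict a response surface for a query triplet
#'
#' Predicts the output embedding for both drug orderings, solves the
#' pre-image problem with the configured solver under the summed
#' dual-ordering objective (so that \code{predict(c, d1, d2)} is exactly
#' the transpose of \code{predict(c, d2, d1)}), and assembles the recovered
#' BRAID surface on the query dose grid, rescaled and clipped to the
#' dataset response scale.
#'
#' @param model a fitted [SurfaceKRModel-class].
#' @param cell,drugA,drugB query triplet ids.
#' @param dosesA,dosesB query dose grid.
#' @param newCellFeatures,newDrugFeatures optional feature matrices (ids as
#'   rownames) for entities unseen in training.
#' @return list: \code{surface} ([ResponseSurface-class]), \code{params}
#'   ([BraidSurface-class]), \code{objective}.
#' @export
predictSurface <- function(model, cell, drugA, drugB, dosesA, dosesB,
                           newCellFeatures = NULL, newDrugFeatures = NULL) {
    cfg <- model@config
    if (cfg$scope == "cell_by_cell") {
        sub <- model@submodels[[cell]]
        if (is.null(sub))
            stop(sprintf("cell-by-cell scope has no model for cell line '%s'",
                         cell))
        return(predictSurface(sub, cell, drugA, drugB, dosesA, dosesB,
                              newCellFeatures, newDrugFeatures))
    }
    emb <- .queryEmbeddings(model, cell, drugA, drugB, newCellFeatures,
                            newDrugFeatures)
    h <- .queryHills(model, cell, drugA, drugB)
    sol <- if (cfg$solver == "candidate") {
        candidatePreimage(emb$g1, model@map, h$a, h$b, cfg$kappaGrid,
                          cfg$deltaGrid, mode = cfg$mode,
                          embeddingSwapped = emb$g2)
    } else {
        pgdPreimage(emb$g1, model@map, h$a, h$b, mode = cfg$mode,
                    steps = cfg$pgdSteps, lr = cfg$pgdLr,
                    embeddingSwapped = emb$g2)
    }
    list(surface = assemblePrediction(sol$params, cell, drugA, drugB,
                                      dosesA, dosesB, model@scale, cfg$mode),
         params = sol$params, objective = sol$objective)
}

#' @rdname predictSurface
#' @param surfaces list of [ResponseSurface-class] objects whose triplets
#'   and grids define the queries (e.g. held-out ground truth).
#' @return \code{predictForSurfaces}: list of [predictSurface()] results.
#' @export
predictForSurfaces <- function(model, surfaces, newCellFeatures = NULL,
                               newDrugFeatures = NULL) {
    lapply(surfaces, function(s)
        predictSurface(model, s@cell, s@drugA, s@drugB, s@dosesA, s@dosesB,
                       newCellFeatures, newDrugFeatures))
}

#' Neutral additive baseline surface
#'
#' The no-learning baseline: the additive BRAID surface (kappa = 0,
#' delta = 1) implied by the triplet's monotherapy Hill fits, evaluated on
#' the query grid. Invariant to the training surfaces.
#'
#' @inheritParams predictSurface
#' @return list with \code{surface} and \code{params}.
#' @export
neutralBaseline <- function(model, cell, drugA, drugB, dosesA, dosesB) {
    h <- .queryHills(model, cell, drugA, drugB)
    params <- neutralSurface(h$a, h$b)
    list(surface = assemblePrediction(params, cell, drugA, drugB, dosesA,
                                      dosesB, model@scale, "direct"),
         params = params)
}

#' Cross-validate the early-stopping iteration count
#'
#' Surface-grouped folds (no surface's measurements are split across train
#' and test); for each candidate iteration count the model is refitted on
#' each training fold and scored by pooled Pearson correlation between
#' predicted and held-out responses; the candidate with the best mean fold
#' correlation wins. Deterministic given the seed.
#'
#' @inheritParams surfaceKR
#' @param nFolds number of folds (>= 2).
#' @param maxIterGrid candidate iteration counts.
#' @param seed fold-assignment seed.
#' @return list: \code{best} (config with the selected maxIter),
#'   \code{results} (data.frame maxIter x mean/sd fold Pearson).
#' @export
crossValidate <- function(x, cellFeatures, drugFeatures,
                          config = surfaceKRConfig(),
                          nFolds = 3L, maxIterGrid = c(3L, 5L, 10L),
                          seed = 1L, scale = responseScale(0, 1)) {
    stopifnot(nFolds >= 2L)
    prep <- .prepareTraining(x, cellFeatures, drugFeatures, scale,
                             config$minComboCells)
    trip <- data.frame(
        cell = vapply(prep$surfaces, function(s) s@cell, character(1)),
        drugA = vapply(prep$surfaces, function(s) s@drugA, character(1)),
        drugB = vapply(prep$surfaces, function(s) s@drugB, character(1)))
    splits <- makeSplits(trip, "new_combo", nSplits = nFolds, seed = seed)
    if (length(maxIterGrid) == 1L) {
        cfg <- config; cfg$maxIter <- as.integer(maxIterGrid)
        return(list(best = cfg,
                    results = data.frame(maxIter = maxIterGrid, pearson = NA,
                                         sd = NA)))
    }
    res <- data.frame(maxIter = maxIterGrid, pearson = NA_real_, sd = NA_real_)
    for (g in seq_along(maxIterGrid)) {
        cfg <- config; cfg$maxIter <- as.integer(maxIterGrid[g])
        folds <- numeric(0)
        for (f in seq_along(splits$folds)) {
            fold <- splits$folds[[f]]
            if (length(fold$test) == 0L) stop("fold with no surfaces")
            m <- .fitCore(prep, cfg, trainIdx = fold$train)
            preds <- predictForSurfaces(m, prep$surfaces[fold$test])
            ev <- evaluatePredictions(lapply(preds, `[[`, "surface"),
                                      prep$surfaces[fold$test])
            folds <- c(folds, ev$pearson)
        }
        res$pearson[g] <- mean(folds); res$sd[g] <- sd(folds)
    }
    best <- config
    best$maxIter <- as.integer(res$maxIter[which.max(res$pearson)])
    list(best = best, results = res)
}
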