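#' Simulate a drug-combination screen with known ground truth
#'
#' Generates a synthetic dataset that mirrors the structure of public
#' combination screens: per-(cell, drug) monotherapy Hill curves, small
#' rectangular combination dose grids, and a per-triplet interaction
#' strength kappa that is mostly additive with heavier synergy/antagonism
#' tails — the empirical hallmark of real screens. In the
#' \code{"feature_linked"} model kappa varies smoothly with the features: a
#' standardized bilinear form of the cell features and the two drugs'
#' fingerprint difference, soft-thresholded so roughly 70 percent of
#' triplets are near-additive (|kappa| < 0.3). Responses are BRAID values
#' plus Gaussian noise, clipped to the unit scale.
#'
#' Defaults are the reference study conditions used throughout the package
#' tests: 5 cell lines x 8 drugs on 4x4 grids with noise 0.05.
#'
#' @param nCells,nDrugs entity counts.
#' @param gridSize length-2 integer vector, combination grid shape.
#' @param noiseSd response noise standard deviation (unit scale).
#' @param kappaModel \code{"feature_linked"} or \code{"zero"} (all
#'   additive).
#' @param fingerprintLen drug fingerprint length.
#' @param nCellFeatures continuous cell feature dimension.
#' @param seed RNG seed (the generator is fully seeded and deterministic).
#' @return list: \code{table} (long-format response table),
#'   \code{cellFeatures}, \code{drugFingerprints}, \code{scale}, and
#'   \code{truth} (hill parameter table, per-triplet kappa, the spec).
#' @export
simulateComboData <- function(nCells = 5L, nDrugs = 8L, gridSize = c(4L, 4L),
                              noiseSd = 0.05,
                              kappaModel = c("feature_linked", "zero"),
                              fingerprintLen = 64L, nCellFeatures = 10L,
                              seed = 1L) {
    kappaModel <- match.arg(kappaModel)
    stopifnot(nCells >= 1L, nDrugs >= 2L, all(gridSize >= 2L), noiseSd >= 0)
    set.seed(seed)
    cells <- sprintf("cell%02d", seq_len(nCells))
    drugs <- sprintf("drug%02d", seq_len(nDrugs))

    fps <- matrix(rbinom(nDrugs * fingerprintLen, 1L, 0.3), nDrugs,
                  dimnames = list(drugs, NULL))
    fps[rowSums(fps) == 0L, 1L] <- 1L
    cellFeat <- matrix(rnorm(nCells * nCellFeatures), nCells,
                       dimnames = list(cells, NULL))

    # per-(cell, drug) monotherapy truth
    hills <- vector("list", nCells * nDrugs)
    names(hills) <- as.vector(outer(cells, drugs, .hillKey))
    hillTab <- expand.grid(cell = cells, drug = drugs,
                           stringsAsFactors = FALSE)
    hillTab$ec50 <- 10^runif(nrow(hillTab), -2, 1)
    hillTab$n <- runif(nrow(hillTab), 0.5, 3)
    hillTab$e0 <- 1
    hillTab$emax <- runif(nrow(hillTab), 0, 0.6)
    for (i in seq_len(nrow(hillTab)))
        hills[[.hillKey(hillTab$cell[i], hillTab$drug[i])]] <-
            HillCurve(hillTab$e0[i], hillTab$emax[i], hillTab$ec50[i],
                      hillTab$n[i])

    # fixed per-drug dose ranges around the drug's typical potency
    doseMult <- function(k) exp(seq(log(1/8), log(8), length.out = k))
    drugDoses <- lapply(drugs, function(d) {
        gm <- exp(mean(log(hillTab$ec50[hillTab$drug == d])))
        gm * doseMult(max(gridSize))
    })
    names(drugDoses) <- drugs

    # feature-linked interaction strength, symmetric in the drug pair
    pairs <- t(utils::combn(nDrugs, 2))
    trip <- expand.grid(ci = seq_len(nCells), pi = seq_len(nrow(pairs)))
    trip$cell <- cells[trip$ci]
    trip$drugA <- drugs[pairs[trip$pi, 1]]
    trip$drugB <- drugs[pairs[trip$pi, 2]]
    if (kappaModel == "zero") {
        trip$kappa <- 0
    } else {
        W <- matrix(rnorm(nCellFeatures * fingerprintLen), nCellFeatures)
        raw <- vapply(seq_len(nrow(trip)), function(i) {
            vdiff <- abs(fps[trip$drugA[i], ] - fps[trip$drugB[i], ])
            drop(cellFeat[trip$cell[i], ] %*% W %*% vdiff)
        }, numeric(1))
        z <- (raw - mean(raw)) / sd(raw)
        trip$kappa <- pmin(pmax(3 * sign(z) * pmax(abs(z) - 1, 0), -1.9), 8)
    }

    noise <- function(m) m + rnorm(length(m), sd = noiseSd)
    clip <- function(v) pmin(pmax(v, 0), 1)

    rows <- vector("list", nrow(trip) + nrow(hillTab))
    r <- 0L
    # monotherapy rows: the drug's combination doses plus flanking doses
    for (i in seq_len(nrow(hillTab))) {
        d <- drugDoses[[hillTab$drug[i]]]
        d <- sort(unique(c(d, min(d) / 4, max(d) * 4)))
        resp <- clip(noise(hillResponse(
            hills[[.hillKey(hillTab$cell[i], hillTab$drug[i])]], d)))
        r <- r + 1L
        rows[[r]] <- data.frame(cell_id = hillTab$cell[i],
                                drug_a = hillTab$drug[i], drug_b = "",
                                conc_a = d, conc_b = 0, response = resp)
    }
    # combination rows on the rectangular grid
    for (i in seq_len(nrow(trip))) {
        hA <- hills[[.hillKey(trip$cell[i], trip$drugA[i])]]
        hB <- hills[[.hillKey(trip$cell[i], trip$drugB[i])]]
        bs <- BraidSurface(hA, hB, kappa = trip$kappa[i], delta = 1)
        da <- drugDoses[[trip$drugA[i]]][seq_len(gridSize[1])]
        db <- drugDoses[[trip$drugB[i]]][seq_len(gridSize[2])]
        g <- expand.grid(conc_a = da, conc_b = db)
        resp <- clip(noise(braidResponse(bs, g$conc_a, g$conc_b)))
        r <- r + 1L
        rows[[r]] <- data.frame(cell_id = trip$cell[i],
                                drug_a = trip$drugA[i],
                                drug_b = trip$drugB[i],
                                conc_a = g$conc_a, conc_b = g$conc_b,
                                response = resp)
    }
    table <- do.call(rbind, rows)
    list(table = table, cellFeatures = cellFeat, drugFingerprints = fps,
         scale = responseScale(0, 1),
         truth = list(hills = hillTab,
                      kappa = trip[, c("cell", "drugA", "drugB", "kappa")],
                      spec = list(nCells = nCells, nDrugs = nDrugs,
                                  gridSize = gridSize, noiseSd = noiseSd,
                                  kappaModel = kappaModel, seed = seed)))
}

#' Ground-truth recovery report for a fitted model
#'
#' Scores predictions against a simulation's hidden truth: per-surface
#' interaction recovery error and RMSE, the same for the neutral baseline,
#' and pooled Pearson correlations.
#'
#' @param sim result of [simulateComboData()].
#' @param predictions list of [predictSurface()] results (with
#'   \code{params}).
#' @param truthSurfaces matched list of measured [ResponseSurface-class]
#'   objects.
#' @param model the fitted [SurfaceKRModel-class] (for the baseline).
#' @return list: \code{perSurface} data.frame and \code{summary} list.
#' @export
recoveryReport <- function(sim, predictions, truthSurfaces, model) {
    stopifnot(length(predictions) == length(truthSurfaces))
    kap <- sim$truth$kappa
    kapKey <- paste(kap$cell, kap$drugA, kap$drugB)
    out <- data.frame()
    basePred <- list(); surfPred <- list()
    for (i in seq_along(truthSurfaces)) {
        s <- truthSurfaces[[i]]
        p <- predictions[[i]]
        base <- neutralBaseline(model, s@cell, s@drugA, s@drugB, s@dosesA,
                                s@dosesB)
        basePred[[i]] <- base$surface
        surfPred[[i]] <- p$surface
        kTrue <- kap$kappa[match(paste(s@cell, s@drugA, s@drugB), kapKey)]
        ok <- is.finite(s@values)
        out <- rbind(out, data.frame(
            cell = s@cell, drugA = s@drugA, drugB = s@drugB,
            kappaTrue = kTrue, kappaPred = p$params@kappa,
            kappaErr = p$params@kappa - kTrue,
            rmse = sqrt(mean((p$surface@values[ok] - s@values[ok])^2)),
            rmseNeutral = sqrt(mean((base$surface@values[ok] - s@values[ok])^2))))
    }
    ev <- evaluatePredictions(surfPred, truthSurfaces)
    evBase <- evaluatePredictions(basePred, truthSurfaces)
    list(perSurface = out,
         summary = list(pearson = ev$pearson, pearsonNeutral = evBase$pearson,
                        rmseMean = ev$rmseMean,
                        rmseNeutralMean = evBase$rmseMean,
                        kappaMAE = mean(abs(out$kappaErr))))
}
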