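#' Load a long-format dose-response table
#'
#' Reads (or accepts) a table with columns \code{cell_id, drug_a, drug_b,
#' conc_a, conc_b, response} and optional \code{replicate}; replicate
#' measurements of the same (cell, drug pair, dose pair) are collapsed by
#' their median. Rows with one zero concentration are monotherapy
#' measurements and are routed to Hill fitting; rows with both
#' concentrations positive form the combination surfaces. Surfaces with
#' fewer than \code{minComboCells} measured combination cells are dropped.
#'
#' @param x file path of a CSV, or a data.frame already in long format.
#' @param scale the dataset [ResponseScale-class] (e.g.
#'   \code{responseScale(0, 100)} for percent growth).
#' @param minComboCells minimum measured combination cells per surface.
#' @return list: \code{table} (collapsed long table), \code{monotherapy}
#'   (data.frame cell, drug, dose, response), \code{surfaces} (list of
#'   [ResponseSurface-class]), \code{dropped} (surfaces dropped as too
#'   small).
#' @export
loadResponseTable <- function(x, scale = responseScale(0, 1),
                              minComboCells = 4L) {
    tab <- if (is.character(x)) read.csv(x, stringsAsFactors = FALSE) else x
    req <- c("cell_id", "drug_a", "drug_b", "conc_a", "conc_b", "response")
    miss <- setdiff(req, names(tab))
    if (length(miss))
        stop("missing required columns: ", paste(miss, collapse = ", "))
    for (col in c("conc_a", "conc_b", "response")) {
        v <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(v) & !is.na(tab[[col]]))
        if (length(bad))
            stop(sprintf("non-numeric '%s' in rows: %s", col,
                         paste(utils::head(bad, 5), collapse = ", ")))
        tab[[col]] <- v
    }
    bad <- which(is.na(tab$conc_a) | is.na(tab$conc_b) | tab$conc_a < 0 |
                 tab$conc_b < 0)
    if (length(bad))
        stop("missing or negative concentrations in rows: ",
             paste(utils::head(bad, 5), collapse = ", "))

    tab <- aggregate(response ~ cell_id + drug_a + drug_b + conc_a + conc_b,
                     data = tab, FUN = median)

    monoA <- tab$conc_b == 0 & tab$conc_a > 0
    monoB <- tab$conc_a == 0 & tab$conc_b > 0
    ctrl  <- tab$conc_a == 0 & tab$conc_b == 0
    mono <- rbind(
        data.frame(cell = tab$cell_id[monoA], drug = tab$drug_a[monoA],
                   dose = tab$conc_a[monoA], response = tab$response[monoA]),
        data.frame(cell = tab$cell_id[monoB], drug = tab$drug_b[monoB],
                   dose = tab$conc_b[monoB], response = tab$response[monoB]),
        data.frame(cell = rep(tab$cell_id[ctrl], 2),
                   drug = c(tab$drug_a[ctrl], tab$drug_b[ctrl]),
                   dose = rep(0, 2 * sum(ctrl)),
                   response = rep(tab$response[ctrl], 2)))

    combo <- tab[tab$conc_a > 0 & tab$conc_b > 0, , drop = FALSE]
    surfaces <- list(); dropped <- 0L
    if (nrow(combo)) {
        key <- paste(combo$cell_id, combo$drug_a, combo$drug_b, sep = "\r")
        for (k in unique(key)) {
            rows <- combo[key == k, , drop = FALSE]
            da <- sort(unique(rows$conc_a)); db <- sort(unique(rows$conc_b))
            vals <- matrix(NA_real_, length(da), length(db))
            vals[cbind(match(rows$conc_a, da), match(rows$conc_b, db))] <-
                rows$response
            if (sum(is.finite(vals)) < minComboCells) {
                dropped <- dropped + 1L
                next
            }
            surfaces[[length(surfaces) + 1L]] <-
                responseSurface(rows$cell_id[1], rows$drug_a[1],
                                rows$drug_b[1], da, db, vals, scale)
        }
    }
    if (length(surfaces) == 0L)
        message("no combination surfaces found (monotherapy-only input?)")
    if (dropped > 0L)
        message(sprintf("dropped %d surfaces with fewer than %d combination cells",
                        dropped, minComboCells))
    list(table = tab, monotherapy = mono, surfaces = surfaces,
         dropped = dropped)
}

#' Export / import fitted surface parameters
#'
#' One row per triplet with all BRAID parameters, as a plain CSV.
#'
#' @param surfaces list of [ResponseSurface-class] (for the triplet ids).
#' @param braids matched list of fitted [BraidSurface-class].
#' @param path CSV path.
#' @return \code{readBraidFits} returns the data.frame.
#' @export
writeBraidFits <- function(surfaces, braids, path) {
    stopifnot(length(surfaces) == length(braids))
    rows <- lapply(seq_along(braids), function(i) {
        tr <- surfaceTriplet(surfaces[[i]])
        data.frame(cell = tr["cell"], drug_a = tr["drugA"], drug_b = tr["drugB"],
                   t(braidCoef(braids[[i]])), row.names = NULL)
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeBraidFits
#' @export
readBraidFits <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' MACCS substructure fingerprints from SMILES
#'
#' Computes the standard 166-key MACCS binary fingerprints through
#' OpenBabel (package \pkg{ChemmineOB}). Unparseable or featureless SMILES
#' are reported and dropped.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional ids used as rownames (default the SMILES).
#' @return binary matrix, one 166-column row per successfully parsed SMILES.
#' @export
fingerprintsFromSmiles <- function(smiles, ids = smiles) {
    if (length(smiles) == 0L) stop("no SMILES given")
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
        stop("package 'ChemmineOB' is required to compute MACCS fingerprints")
    stopifnot(length(ids) == length(smiles))
    out <- matrix(0L, 0L, 166L)
    kept <- character(0)
    for (i in seq_along(smiles)) {
        fp <- try(suppressWarnings(ChemmineOB::fingerprint_OB(
            ChemmineOB::forEachMol("SMILES", smiles[i], identity), "MACCS")),
            silent = TRUE)
        if (inherits(fp, "try-error") || length(fp) < 166L || sum(fp) == 0) {
            warning(sprintf("dropping unparseable or featureless SMILES '%s'",
                            smiles[i]))
            next
        }
        out <- rbind(out, as.integer(fp[1:166] != 0))
        kept <- c(kept, ids[i])
    }
    if (nrow(out) == 0L) stop("no SMILES could be parsed")
    rownames(out) <- kept
    out
}

#' Combinatorial coverage of a combination screen
#'
#' Number of possible (cell line, unordered drug pair) surfaces and the
#' percentage actually measured, exact rational arithmetic before the final
#' one-decimal rounding.
#'
#' @param nCells,nDrugs,nSurfaces positive counts.
#' @return list: \code{possible}, \code{percent} (one decimal).
#' @examples
#' datasetStats(60, 104, 311527)  # a dense screen: ~96.9% coverage
#' @export
datasetStats <- function(nCells, nDrugs, nSurfaces) {
    stopifnot(nCells >= 1, nDrugs >= 2, nSurfaces >= 0)
    possible <- nCells * nDrugs * (nDrugs - 1) / 2
    if (nSurfaces > possible)
        stop("more surfaces than possible combinations")
    list(possible = possible, percent = round(100 * nSurfaces / possible, 1))
}

#' Scenario-respecting train/test splits
#'
#' Splits surfaces by triplet under one of three predictive scenarios of
#' increasing difficulty: \code{new_combo} (random surface-level folds; all
#' entities remain in training), \code{new_drug} (per fold a set of
#' (cell, drug) pairs is held out; test surfaces have exactly one of their
#' two (cell, drug) pairs unseen), \code{new_cell_line} (whole cell lines
#' held out). Deterministic given the seed. [auditSplits()] verifies the
#' scenario constraint on every fold.
#'
#' @param triplets data.frame with columns \code{cell}, \code{drugA},
#'   \code{drugB} (one row per surface).
#' @param scenario one of \code{"new_combo"}, \code{"new_drug"},
#'   \code{"new_cell_line"}.
#' @param nSplits number of folds.
#' @param seed RNG seed.
#' @param pairFraction for \code{new_drug}: fraction of (cell, drug) pairs
#'   held out per fold.
#' @return list with \code{scenario} and \code{folds}, each fold a list of
#'   \code{train} / \code{test} surface indices.
#' @export
makeSplits <- function(triplets, scenario = c("new_combo", "new_drug",
                                              "new_cell_line"),
                       nSplits = 5L, seed = 1L, pairFraction = 0.2) {
    scenario <- match.arg(scenario)
    n <- nrow(triplets)
    stopifnot(n >= nSplits)
    set.seed(seed)
    folds <- vector("list", nSplits)
    if (scenario == "new_combo") {
        perm <- sample.int(n)
        assign <- rep(seq_len(nSplits), length.out = n)[order(perm)]
        for (f in seq_len(nSplits))
            folds[[f]] <- list(train = which(assign != f),
                               test = which(assign == f))
    } else if (scenario == "new_cell_line") {
        cells <- unique(triplets$cell)
        if (length(cells) < nSplits)
            stop("fewer cell lines than requested folds")
        assign <- rep(seq_len(nSplits), length.out = length(cells))[
            order(sample.int(length(cells)))]
        for (f in seq_len(nSplits)) {
            testCells <- cells[assign == f]
            folds[[f]] <- list(train = which(!triplets$cell %in% testCells),
                               test = which(triplets$cell %in% testCells))
        }
    } else {
        pairs <- unique(rbind(
            data.frame(cell = triplets$cell, drug = triplets$drugA),
            data.frame(cell = triplets$cell, drug = triplets$drugB)))
        nHold <- max(1L, round(pairFraction * nrow(pairs)))
        keyA <- paste(triplets$cell, triplets$drugA)
        keyB <- paste(triplets$cell, triplets$drugB)
        for (f in seq_len(nSplits)) {
            held <- paste(pairs$cell, pairs$drug)[sample.int(nrow(pairs), nHold)]
            nHeld <- (keyA %in% held) + (keyB %in% held)
            if (!any(nHeld == 1L) || !any(nHeld == 0L))
                stop("new_drug constraint unsatisfiable with this pairFraction")
            folds[[f]] <- list(train = which(nHeld == 0L),
                               test = which(nHeld == 1L))
        }
    }
    for (f in seq_len(nSplits))
        if (length(folds[[f]]$train) == 0L || length(folds[[f]]$test) == 0L)
            stop("empty train or test fold; adjust nSplits")
    list(scenario = scenario, folds = folds)
}

#' @rdname makeSplits
#' @param splits result of [makeSplits()].
#' @return \code{auditSplits}: TRUE invisibly, or an error describing the
#'   violated constraint.
#' @export
auditSplits <- function(splits, triplets) {
    for (f in seq_along(splits$folds)) {
        tr <- splits$folds[[f]]$train; te <- splits$folds[[f]]$test
        if (length(intersect(tr, te)))
            stop(sprintf("fold %d: train/test overlap", f))
        if (splits$scenario == "new_combo") {
            if (length(union(tr, te)) != nrow(triplets))
                stop(sprintf("fold %d: surfaces lost", f))
        } else if (splits$scenario == "new_cell_line") {
            if (length(intersect(triplets$cell[tr], triplets$cell[te])))
                stop(sprintf("fold %d: test cell line seen in training", f))
        } else {
            trainPairs <- unique(c(paste(triplets$cell[tr], triplets$drugA[tr]),
                                   paste(triplets$cell[tr], triplets$drugB[tr])))
            seenA <- paste(triplets$cell[te], triplets$drugA[te]) %in% trainPairs
            seenB <- paste(triplets$cell[te], triplets$drugB[te]) %in% trainPairs
            if (any(seenA & seenB))
                stop(sprintf("fold %d: test surface with both pairs seen", f))
        }
    }
    invisible(TRUE)
}

#' Read feature matrices for the command-line tools
#'
#' \code{readCellFeatures} reads a TSV with the entity id in the first
#' column and numeric features in the rest. \code{readDrugFeatures} reads
#' either the same TSV layout (precomputed fingerprints/features) or a
#' two-column CSV \code{drug_id, smiles} from which MACCS fingerprints are
#' computed.
#'
#' @param path input file.
#' @param type \code{"tsv"} for a feature table, \code{"smiles"} for a
#'   SMILES list.
#' @return numeric matrix with ids as rownames.
#' @export
readCellFeatures <- function(path) {
    tab <- read.csv(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(tab[[1]])
    m
}

#' @rdname readCellFeatures
#' @export
readDrugFeatures <- function(path, type = c("tsv", "smiles")) {
    type <- match.arg(type)
    if (type == "tsv") return(readCellFeatures(path))
    tab <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("drug_id", "smiles") %in% names(tab)))
        stop("SMILES input needs columns drug_id, smiles")
    fingerprintsFromSmiles(tab$smiles, ids = tab$drug_id)
}
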