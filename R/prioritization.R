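#' Neighborhood weighting scores
#'
#' Guilt-by-association scoring: every network gene outside the seed set
#' receives the sum of the weights of its direct links to the seed genes. A
#' gene with no links to any seed scores exactly 0. Seed genes absent from the
#' network are dropped with a warning; if none remain the scoring is
#' undefined.
#'
#' @param net a [WeightedNetwork-class] background network.
#' @param seeds character vector of seed gene identifiers.
#' @return named numeric vector of scores over all non-seed network genes.
#' @export
neighborhoodScores <- function(net, seeds) {
    stopifnot(is(net, "WeightedNetwork"))
    seeds <- unique(as.character(seeds))
    if (length(seeds) == 0) stop("empty seed set", call. = FALSE)
    absent <- setdiff(seeds, net@nodes)
    if (length(absent)) {
        warning(length(absent), " seed gene(s) absent from the network: ",
                paste(utils::head(absent, 5L), collapse = ", "),
                if (length(absent) > 5) ", ...")
        seeds <- setdiff(seeds, absent)
    }
    if (length(seeds) == 0)
        stop("no seed gene is present in the network", call. = FALSE)
    candidates <- setdiff(net@nodes, seeds)
    scores <- setNames(numeric(length(candidates)), candidates)
    ed <- net@edges
    # each edge contributes its weight to the non-seed endpoint when the
    # other endpoint is a seed
    fromSeed <- ed$from %in% seeds
    toSeed <- ed$to %in% seeds
    hit <- fromSeed & !toSeed
    if (any(hit)) {
        s <- tapply(ed$weight[hit], ed$to[hit], sum)
        scores[names(s)] <- scores[names(s)] + as.numeric(s)
    }
    hit <- toSeed & !fromSeed
    if (any(hit)) {
        s <- tapply(ed$weight[hit], ed$from[hit], sum)
        scores[names(s)] <- scores[names(s)] + as.numeric(s)
    }
    scores
}

# worst (maximum) rank within each tie group of a descending ranking
.worstRank <- function(scores) {
    n <- length(scores)
    n - rank(scores, ties.method = "min") + 1
}

#' Rank candidate genes by score
#'
#' Orders candidates by decreasing score. Tied genes all receive the worst
#' (largest) rank of their tie group — the conservative convention that
#' honestly penalizes the common plateau of zero-scoring genes. Listing order
#' within a tie group is alphabetical for reproducible output.
#'
#' @param scores named numeric vector, as returned by [neighborhoodScores()].
#' @param seeds seed genes (must not appear among the scored candidates).
#' @return a [RankedList-class].
#' @examples
#' rankCandidates(c(a = 0.9, b = 0.5, c = 0.5, d = 0.1))
#' @export
rankCandidates <- function(scores, seeds = character()) {
    if (length(scores) == 0) stop("no candidates to rank", call. = FALSE)
    if (is.null(names(scores)) || any(!nzchar(names(scores))))
        stop("'scores' must be named by gene", call. = FALSE)
    if (any(names(scores) %in% seeds))
        stop("seed genes must not appear among the candidates", call. = FALSE)
    rk <- .worstRank(scores)
    o <- order(-scores, names(scores))
    new("RankedList",
        entries = data.frame(gene = names(scores)[o], score = unname(scores[o]),
                             rank = unname(rk[o])),
        tiePolicy = "worst")
}

#' Ranked entries as a data frame
#'
#' @param x a [RankedList-class].
#' @return `data.frame` with columns `gene`, `score`, `rank`.
#' @export
rankedEntries <- function(x) {
    stopifnot(is(x, "RankedList"))
    x@entries
}

setMethod("show", "RankedList", function(object) {
    cat("RankedList:", nrow(object@entries), "candidates (tie policy:",
        object@tiePolicy, ")\n")
    print(utils::head(object@entries, 5L), row.names = FALSE)
    if (nrow(object@entries) > 5) cat("  ...\n")
})

#' @rdname accessors
#' @export
setMethod("pooledRecords", "PooledRanks", function(x) x@records)

setMethod("show", "PooledRanks", function(object) {
    r <- object@records
    cat("PooledRanks:", nrow(r), "test cases over",
        length(unique(r$set)), "set(s)\n")
    if (nrow(r) > 0)
        cat(sprintf("  median rank %g of median pool size %g\n",
                    stats::median(r$rank), stats::median(r$nCandidates)))
})

#' Leave-one-out cross-validation of disease gene ranking
#'
#' For every disease set with at least 3 member genes present in the network,
#' each member gene is held out in turn, the remaining members are used as
#' seeds, and the held-out gene is ranked among all non-seed network genes by
#' its neighborhood score. Records from all sets are pooled. Sets with fewer
#' than 3 network genes are skipped with a warning; member genes absent from
#' the network are skipped silently within otherwise usable sets.
#'
#' @param net a [WeightedNetwork-class] background network.
#' @param collection a [DiseaseGeneCollection-class].
#' @return a [PooledRanks-class] with one record per (set, held-out gene).
#' @export
leaveOneOut <- function(net, collection) {
    stopifnot(is(net, "WeightedNetwork"), is(collection, "DiseaseGeneCollection"))
    records <- list()
    skipped <- character()
    for (lab in names(collection@sets)) {
        present <- intersect(collection@sets[[lab]], net@nodes)
        if (length(present) < 3) {
            skipped <- c(skipped, lab)
            next
        }
        for (g in present) {
            seeds <- setdiff(present, g)
            scores <- neighborhoodScores(net, seeds)
            rk <- .worstRank(scores)
            records[[length(records) + 1L]] <- data.frame(
                set = lab, gene = g, rank = unname(rk[g]),
                nCandidates = length(scores))
        }
    }
    if (length(skipped))
        warning(length(skipped), " set(s) with fewer than 3 network genes skipped: ",
                paste(utils::head(skipped, 5L), collapse = ", "),
                if (length(skipped) > 5) ", ...")
    if (length(records) == 0)
        stop("no usable gene set (need >= 3 genes present in the network)",
             call. = FALSE)
    new("PooledRanks", records = do.call(rbind, records))
}

#' Rank unseen test genes against a seed set
#'
#' Scores all non-seed network genes by their neighborhood score against the
#' seeds and records the rank of every test gene present in the network —
#' the new-disease-gene prediction protocol. Seed and test sets must be
#' disjoint.
#'
#' @param net a [WeightedNetwork-class] background network.
#' @param seeds character vector of known disease genes.
#' @param testGenes character vector of putative disease genes, disjoint from
#'   `seeds`.
#' @param label set label used in the pooled records (default `"test"`).
#' @return a [PooledRanks-class] with one record per test gene in the network.
#' @export
predictNewGenes <- function(net, seeds, testGenes, label = "test") {
    stopifnot(is(net, "WeightedNetwork"))
    seeds <- unique(as.character(seeds))
    testGenes <- unique(as.character(testGenes))
    if (length(intersect(seeds, testGenes)))
        stop("seed and test sets must be disjoint", call. = FALSE)
    scores <- neighborhoodScores(net, seeds)
    rk <- .worstRank(scores)
    inNet <- testGenes[testGenes %in% names(scores)]
    if (length(inNet) < length(testGenes))
        warning(length(testGenes) - length(inNet),
                " test gene(s) absent from the network were skipped")
    if (length(inNet) == 0)
        stop("no test gene is present in the network", call. = FALSE)
    new("PooledRanks",
        records = data.frame(set = label, gene = inNet,
                             rank = unname(rk[inNet]),
                             nCandidates = length(scores)))
}

#' Top-k recovery curve
#'
#' Fraction (as a percentage) of pooled test cases whose rank is at or below
#' each cutoff k = 0 .. `kmax` — the precision-within-top-k summary reported
#' over the window `[0, 100]`.
#'
#' @param pooled a [PooledRanks-class].
#' @param kmax largest rank cutoff (default 100).
#' @return `data.frame` with columns `k` and `percent` (non-decreasing).
#' @export
topkCurve <- function(pooled, kmax = 100L) {
    stopifnot(is(pooled, "PooledRanks"))
    r <- pooled@records$rank
    if (length(r) == 0) stop("no pooled records", call. = FALSE)
    k <- 0:kmax
    data.frame(k = k,
               percent = 100 * vapply(k, function(kk) mean(r <= kk), 0))
}

#' Pooled ROC curve and AUC
#'
#' Builds the pooled receiver-operating-characteristic curve over rank
#' cutoffs. Each record contributes one positive (the held-out or test gene at
#' its rank) and `nCandidates - 1` negatives; pools of different sizes are
#' made commensurable through normalized ranks. Sweeping the normalized
#' cutoff t, the true positive rate is the fraction of positives ranked at or
#' above the cutoff and the false positive rate is the average fraction of
#' negatives above it. Curve vertices are placed just before and at every
#' positive's rank, so trapezoidal integration gives the exact area: for a
#' single record it reduces to the Mann-Whitney statistic
#' `(n - r) / (n - 1)`, and uniformly random ranks give 0.5 in expectation.
#'
#' @param pooled a [PooledRanks-class]; every record needs
#'   `nCandidates >= 2`.
#' @return a [RocCurve-class].
#' @export
rocCurve <- function(pooled) {
    stopifnot(is(pooled, "PooledRanks"))
    rec <- pooled@records
    if (nrow(rec) == 0) stop("no pooled records", call. = FALSE)
    r <- rec$rank
    n <- rec$nCandidates
    if (any(n < 2))
        stop("ROC requires at least 2 candidates per record", call. = FALSE)
    thr <- sort(unique(c(0, (r - 1) / n, r / n, 1)))
    tpr <- fpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
        k <- floor(thr[i] * n + 1e-9)
        hit <- r <= k
        tpr[i] <- mean(hit)
        fpr[i] <- mean((k - hit) / (n - 1))
    }
    aucVal <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    new("RocCurve", points = data.frame(fpr = fpr, tpr = tpr), auc = aucVal)
}

#' @rdname accessors
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname accessors
#' @export
setMethod("rocPoints", "RocCurve", function(x) x@points)

setMethod("show", "RocCurve", function(object) {
    cat(sprintf("RocCurve: %d points, AUC = %.4f\n", nrow(object@points),
                object@auc))
})
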