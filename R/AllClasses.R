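#' @import methods
NULL

#' Weighted gene association network
#'
#' An undirected graph of genes with a positive association score on every
#' edge. Edges are stored in canonical orientation (`from` sorts before `to`),
#' so `{a, b}` and `{b, a}` denote the same edge and self-loops are not
#' representable. Weights of a freshly read network may exceed 1; after
#' [normalizeWeights()] they lie in `(0, 1]` as all downstream stages require.
#'
#' @slot nodes character vector of gene identifiers (Entrez-style tokens;
#'   no whitespace, compared by exact string equality).
#' @slot edges `data.frame` with columns `from`, `to` (character, canonical
#'   order) and `weight` (positive finite numeric).
#'
#' @seealso [weightedNetwork()], [readWeightedEdgeList()], [normalizeWeights()]
#' @export
setClass("WeightedNetwork",
    representation(nodes = "character", edges = "data.frame"))

setValidity("WeightedNetwork", function(object) {
    msg <- character()
    ed <- object@edges
    if (!all(c("from", "to", "weight") %in% names(ed)))
        return("edges must have columns 'from', 'to', 'weight'")
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicated node identifiers")
    if (any(grepl("[[:space:]]", object@nodes)) || any(!nzchar(object@nodes)))
        msg <- c(msg, "node identifiers must be non-empty and whitespace-free")
    if (nrow(ed) > 0) {
        if (!is.character(ed$from) || !is.character(ed$to))
            msg <- c(msg, "edge endpoints must be character")
        if (any(ed$from >= ed$to))
            msg <- c(msg, "edges must be canonically ordered (from < to) with no self-loops")
        if (anyDuplicated(paste(ed$from, ed$to, sep = "\t")))
            msg <- c(msg, "duplicated edges")
        if (!all(c(ed$from, ed$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints missing from the node set")
        if (!is.numeric(ed$weight) || any(!is.finite(ed$weight)) || any(ed$weight <= 0))
            msg <- c(msg, "edge weights must be finite and > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Named disease gene sets
#'
#' A collection of phenotype-labelled gene sets (OMIM-style), as read from a
#' GMT file. Sets smaller than the minimum usable seed-set size (3 genes) are
#' retained but can be listed with [flaggedSets()].
#'
#' @slot sets named list of character vectors (unique gene identifiers).
#' @slot descriptions named character vector, one free-text description per set.
#'
#' @seealso [readGeneSets()], [diseaseGeneCollection()]
#' @export
setClass("DiseaseGeneCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("DiseaseGeneCollection", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || any(!nzchar(names(object@sets))))
        msg <- c(msg, "every gene set must be named")
    if (anyDuplicated(names(object@sets)))
        msg <- c(msg, "duplicated set labels")
    if (any(vapply(object@sets, length, 1L) == 0L))
        msg <- c(msg, "empty gene sets are not allowed")
    if (any(vapply(object@sets, anyDuplicated, 1L) > 0L))
        msg <- c(msg, "gene sets must not contain duplicates")
    if (length(object@descriptions) != length(object@sets))
        msg <- c(msg, "one description per set is required")
    if (length(msg)) msg else TRUE
})

#' Integration parameters
#'
#' Holds the imputation weight epsilon assigned to edges absent from a source,
#' the entropy adjustment exponent theta of the confidence transform, and the
#' inclusive theta grid searched during tuning.
#'
#' @slot epsilon numeric in (0, 0.5); default 0.001.
#' @slot theta positive numeric; default 0.3.
#' @slot thetaGrid strictly increasing positive numeric vector; default
#'   `seq(0.2, 0.6, by = 0.01)`.
#'
#' @seealso [integrationConfig()], [integrateNetworks()], [tuneTheta()]
#' @export
setClass("IntegrationConfig",
    representation(epsilon = "numeric", theta = "numeric", thetaGrid = "numeric"))

setValidity("IntegrationConfig", function(object) {
    msg <- character()
    if (length(object@epsilon) != 1 || !is.finite(object@epsilon) ||
        object@epsilon <= 0 || object@epsilon >= 0.5)
        msg <- c(msg, "epsilon must be a single value in (0, 0.5)")
    if (length(object@theta) != 1 || !is.finite(object@theta) || object@theta <= 0)
        msg <- c(msg, "theta must be a single positive value")
    g <- object@thetaGrid
    if (length(g) < 1 || any(!is.finite(g)) || any(g <= 0) ||
        (length(g) > 1 && any(diff(g) <= 0)))
        msg <- c(msg, "thetaGrid must be strictly increasing and positive")
    if (length(msg)) msg else TRUE
})

#' Edge-union profile of several networks
#'
#' The union edge set of m component networks, with one row of clipped weights
#' per edge: the source weight where the edge exists (clipped into
#' `[epsilon, 1 - epsilon]`), `epsilon` where it is absent. The `observed`
#' matrix records which entries are genuine observations; every union edge is
#' observed in at least one source.
#'
#' @slot edges `data.frame` with canonical `from`/`to` columns, one row per
#'   union edge, sorted.
#' @slot weights numeric matrix, edges x sources, entries in
#'   `[epsilon, 1 - epsilon]`.
#' @slot observed logical matrix parallel to `weights`.
#' @slot networkLabels character, source names in input order.
#' @slot nodes character, union node set.
#' @slot epsilon numeric, the imputation weight used.
#'
#' @seealso [buildUnion()], [integrateNetworks()]
#' @export
setClass("UnionProfile",
    representation(edges = "data.frame", weights = "matrix",
                   observed = "matrix", networkLabels = "character",
                   nodes = "character", epsilon = "numeric"))

setValidity("UnionProfile", function(object) {
    msg <- character()
    ne <- nrow(object@edges)
    m <- length(object@networkLabels)
    if (m < 2)
        msg <- c(msg, "a union profile needs at least 2 source networks")
    if (nrow(object@weights) != ne || nrow(object@observed) != ne)
        msg <- c(msg, "weights/observed must have one row per union edge")
    if (ncol(object@weights) != m || ncol(object@observed) != m)
        msg <- c(msg, "weights/observed must have one column per source")
    eps <- object@epsilon
    if (ne > 0) {
        w <- object@weights
        if (any(w < eps - 1e-12) || any(w > 1 - eps + 1e-12))
            msg <- c(msg, "all profile weights must lie in [epsilon, 1 - epsilon]")
        if (any(rowSums(object@observed) < 1))
            msg <- c(msg, "every union edge must be observed in at least one source")
    }
    if (length(msg)) msg else TRUE
})

#' Theta tuning result
#'
#' Grid-search curve of the squared weight disagreement between the integrated
#' network and a reference network over shared edges, with the minimizing
#' theta.
#'
#' @slot grid theta values evaluated.
#' @slot objective objective value at each grid point (squared-weight units).
#' @slot bestTheta the argmin (ties broken toward the smallest theta).
#' @slot nSharedEdges number of edges shared with the reference.
#'
#' @seealso [tuneTheta()]
#' @export
setClass("ThetaFit",
    representation(grid = "numeric", objective = "numeric",
                   bestTheta = "numeric", nSharedEdges = "integer"))

setValidity("ThetaFit", function(object) {
    msg <- character()
    if (length(object@grid) != length(object@objective))
        msg <- c(msg, "grid and objective lengths differ")
    if (any(object@objective < 0))
        msg <- c(msg, "objective values must be non-negative")
    if (!object@bestTheta %in% object@grid)
        msg <- c(msg, "bestTheta must be a grid point")
    if (object@nSharedEdges < 1L)
        msg <- c(msg, "tuning requires at least one shared edge")
    if (length(msg)) msg else TRUE
})

#' Overlap diagnostics for a set of networks
#'
#' Per-network node/edge counts together with the counts of nodes and edges
#' common to all networks and of the union, plus the per-network fractions of
#' common elements and of union coverage.
#'
#' @slot perNetwork `data.frame` with one row per network: label, node and
#'   edge counts, fraction of the network's nodes/edges that are common to all
#'   networks, and the fraction of union nodes/edges the network covers.
#' @slot commonNodes,commonEdges,unionNodes,unionEdges integer counts.
#'
#' @seealso [overlapReport()]
#' @export
setClass("OverlapReport",
    representation(perNetwork = "data.frame", commonNodes = "integer",
                   commonEdges = "integer", unionNodes = "integer",
                   unionEdges = "integer"))

setValidity("OverlapReport", function(object) {
    msg <- character()
    pn <- object@perNetwork
    if (any(object@commonNodes > pn$nodes) || any(object@commonEdges > pn$edges))
        msg <- c(msg, "common counts cannot exceed per-network counts")
    if (any(object@unionNodes < pn$nodes) || any(object@unionEdges < pn$edges))
        msg <- c(msg, "union counts cannot be below per-network counts")
    fr <- unlist(pn[, grep("^frac", names(pn))], use.names = FALSE)
    if (length(fr) && (any(fr < 0) || any(fr > 1 + 1e-12)))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Ranked candidate genes
#'
#' Candidate genes ordered by decreasing neighborhood score. Ties share the
#' worst (largest) rank in their group; listing order within a tie group is
#' alphabetical so output is reproducible. Seed genes never appear.
#'
#' @slot entries `data.frame` with columns `gene`, `score`, `rank`.
#' @slot tiePolicy label of the rank convention (always `"worst"`).
#'
#' @seealso [rankCandidates()]
#' @export
setClass("RankedList",
    representation(entries = "data.frame", tiePolicy = "character"))

setValidity("RankedList", function(object) {
    msg <- character()
    e <- object@entries
    if (!all(c("gene", "score", "rank") %in% names(e)))
        return("entries must have columns 'gene', 'score', 'rank'")
    if (nrow(e) > 0) {
        if (is.unsorted(rev(e$score)))
            msg <- c(msg, "scores must be non-increasing")
        if (anyDuplicated(e$gene))
            msg <- c(msg, "each candidate must appear exactly once")
        if (any(e$rank < 1) || any(e$rank > nrow(e)))
            msg <- c(msg, "ranks must lie in 1..n")
    }
    if (length(msg)) msg else TRUE
})

#' Pooled rank records from prioritization experiments
#'
#' One record per (disease, held-out or test gene): the 1-based rank the gene
#' achieved among the candidate pool and the pool size. Records from many
#' diseases are pooled for overall evaluation.
#'
#' @slot records `data.frame` with columns `set`, `gene`, `rank`,
#'   `nCandidates`.
#'
#' @seealso [leaveOneOut()], [predictNewGenes()], [rocCurve()], [topkCurve()]
#' @export
setClass("PooledRanks", representation(records = "data.frame"))

setValidity("PooledRanks", function(object) {
    r <- object@records
    if (!all(c("set", "gene", "rank", "nCandidates") %in% names(r)))
        return("records must have columns 'set', 'gene', 'rank', 'nCandidates'")
    if (nrow(r) > 0 && (any(r$rank < 1) || any(r$rank > r$nCandidates)))
        return("ranks must lie in 1..nCandidates")
    TRUE
})

#' ROC curve with AUC
#'
#' Pooled receiver-operating-characteristic curve over rank cutoffs, with the
#' trapezoidal area under the curve.
#'
#' @slot points `data.frame` with columns `fpr`, `tpr`, both non-decreasing,
#'   starting at (0, 0) and ending at (1, 1).
#' @slot auc area under the curve, in `[0, 1]`.
#'
#' @seealso [rocCurve()], [auc()]
#' @export
setClass("RocCurve", representation(points = "data.frame", auc = "numeric"))

setValidity("RocCurve", function(object) {
    msg <- character()
    p <- object@points
    if (!all(c("fpr", "tpr") %in% names(p)))
        return("points must have columns 'fpr', 'tpr'")
    if (nrow(p) < 2)
        msg <- c(msg, "a curve needs at least two points")
    else {
        if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
            msg <- c(msg, "fpr and tpr must be non-decreasing")
        tol <- 1e-9
        if (abs(p$fpr[1]) > tol || abs(p$tpr[1]) > tol ||
            abs(p$fpr[nrow(p)] - 1) > tol || abs(p$tpr[nrow(p)] - 1) > tol)
            msg <- c(msg, "curve must run from (0,0) to (1,1)")
    }
    if (object@auc < -1e-9 || object@auc > 1 + 1e-9)
        msg <- c(msg, "auc must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic fixture specification
#'
#' Parameters of the synthetic-network generator: a latent weighted network is
#' sampled, and each of `mNetworks` observed component networks is an
#' incomplete, noisy view of it.
#'
#' @slot nGenes number of genes (>= 4).
#' @slot mNetworks number of observed component networks (>= 2).
#' @slot edgeDensity probability that a gene pair carries a latent edge.
#' @slot observationNoise standard deviation of the additive Gaussian weight
#'   perturbation applied by each source (weight units).
#' @slot missingness probability that a latent edge is unobserved in a given
#'   source.
#' @slot seed master random seed; all generators are pure functions of
#'   (spec, seed).
#'
#' @seealso [fixtureSpec()], [generateComponentNetworks()]
#' @export
setClass("FixtureSpec",
    representation(nGenes = "integer", mNetworks = "integer",
                   edgeDensity = "numeric", observationNoise = "numeric",
                   missingness = "numeric", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    msg <- character()
    if (object@nGenes < 4L) msg <- c(msg, "nGenes must be >= 4")
    if (object@mNetworks < 2L) msg <- c(msg, "mNetworks must be >= 2")
    if (object@edgeDensity < 0 || object@edgeDensity > 1)
        msg <- c(msg, "edgeDensity must lie in [0, 1]")
    if (object@missingness < 0 || object@missingness > 1)
        msg <- c(msg, "missingness must lie in [0, 1]")
    if (object@observationNoise < 0)
        msg <- c(msg, "observationNoise must be >= 0")
    if (length(msg)) msg else TRUE
})
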