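#' Node and edge overlap across networks
#'
#' Computes, for m >= 2 networks, each network's node and edge counts, the
#' counts common to all networks, the union counts, and the per-network
#' fractions of common elements and of union coverage. These are the standard
#' diagnostics showing that gene association sources share most of their
#' genes but few of their edges.
#'
#' @param nets list of m >= 2 [WeightedNetwork-class] objects (optionally
#'   named).
#' @return an [OverlapReport-class].
#' @export
overlapReport <- function(nets) {
    if (!is.list(nets) || length(nets) < 2)
        stop("overlap report requires at least 2 networks", call. = FALSE)
    if (!all(vapply(nets, is, TRUE, "WeightedNetwork")))
        stop("'nets' must be a list of WeightedNetwork objects", call. = FALSE)
    labels <- names(nets)
    if (is.null(labels) || any(!nzchar(labels)))
        labels <- paste0("net", seq_along(nets))
    nodeSets <- lapply(nets, nodes)
    edgeSets <- lapply(nets, function(n) .edgeKey(n@edges$from, n@edges$to))
    commonNodes <- Reduce(intersect, nodeSets)
    commonEdges <- Reduce(intersect, edgeSets)
    unionNodes <- unique(unlist(nodeSets))
    unionEdges <- unique(unlist(edgeSets))
    perNetwork <- data.frame(
        label = labels,
        nodes = vapply(nodeSets, length, 1L),
        edges = vapply(edgeSets, length, 1L),
        fracCommonNodes = vapply(nodeSets, function(s)
            if (length(s)) length(commonNodes) / length(s) else 0, 0),
        fracCommonEdges = vapply(edgeSets, function(s)
            if (length(s)) length(commonEdges) / length(s) else 0, 0),
        fracOfUnionNodes = vapply(nodeSets, function(s)
            if (length(unionNodes)) length(s) / length(unionNodes) else 0, 0),
        fracOfUnionEdges = vapply(edgeSets, function(s)
            if (length(unionEdges)) length(s) / length(unionEdges) else 0, 0),
        row.names = NULL)
    new("OverlapReport", perNetwork = perNetwork,
        commonNodes = length(commonNodes), commonEdges = length(commonEdges),
        unionNodes = length(unionNodes), unionEdges = length(unionEdges))
}

#' Per-network overlap table
#'
#' @param x an [OverlapReport-class].
#' @return the per-network `data.frame`.
#' @export
overlapTable <- function(x) {
    stopifnot(is(x, "OverlapReport"))
    x@perNetwork
}

setMethod("show", "OverlapReport", function(object) {
    cat("OverlapReport:", nrow(object@perNetwork), "networks\n")
    cat(sprintf("  common: %d nodes, %d edges | union: %d nodes, %d edges\n",
                object@commonNodes, object@commonEdges, object@unionNodes,
                object@unionEdges))
    print(object@perNetwork, row.names = FALSE, digits = 4)
})

#' Aligned weight vectors on shared edges
#'
#' Returns the edge intersection of two networks with both weights, aligned
#' edge-by-edge in canonical order — the input to the weight-agreement
#' correlation.
#'
#' @param netA,netB [WeightedNetwork-class] objects sharing at least 2 edges.
#' @return `data.frame` with columns `from`, `to`, `weightA`, `weightB`.
#' @export
sharedEdgeWeights <- function(netA, netB) {
    stopifnot(is(netA, "WeightedNetwork"), is(netB, "WeightedNetwork"))
    keyA <- .edgeKey(netA@edges$from, netA@edges$to)
    keyB <- .edgeKey(netB@edges$from, netB@edges$to)
    idx <- match(keyA, keyB)
    shared <- which(!is.na(idx))
    if (length(shared) < 2)
        stop("fewer than 2 shared edges between the networks", call. = FALSE)
    data.frame(from = netA@edges$from[shared], to = netA@edges$to[shared],
               weightA = netA@edges$weight[shared],
               weightB = netB@edges$weight[idx[shared]])
}

#' Pearson correlation with t-distribution p-value
#'
#' Standard product-moment correlation of two aligned weight vectors, with the
#' two-sided p-value from the t-distribution on n - 2 degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors, n >= 3, each with non-zero
#'   variance.
#' @return list with elements `r`, `p` and `n`.
#' @export
pearsonCorrelation <- function(x, y) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have equal length", call. = FALSE)
    if (length(x) < 3)
        stop("correlation requires at least 3 pairs", call. = FALSE)
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("zero variance: correlation undefined", call. = FALSE)
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Weight agreement between two networks
#'
#' Pearson correlation (and its p-value) of the edge weights over the shared
#' edges of two networks — the validation that integrated weights remain
#' functionally consistent with an independent reference.
#'
#' @inheritParams sharedEdgeWeights
#' @return list with elements `r`, `p` and `n` (number of shared edges).
#' @export
weightCorrelation <- function(netA, netB) {
    sw <- sharedEdgeWeights(netA, netB)
    pearsonCorrelation(sw$weightA, sw$weightB)
}

#' Mean absolute weight error against a truth network
#'
#' Averages `|w_net - w_truth|` over the edges of the truth network, counting
#' an edge absent from `net` at weight 0 — the same "absent edge carries no
#' association" convention the neighborhood scoring uses. Used to quantify how
#' well a component or integrated network recovers a latent truth.
#'
#' @param net the network under evaluation.
#' @param truth the reference [WeightedNetwork-class] whose edges define the
#'   comparison set.
#' @return mean absolute error (weight units).
#' @export
meanAbsoluteWeightError <- function(net, truth) {
    stopifnot(is(net, "WeightedNetwork"), is(truth, "WeightedNetwork"))
    if (numEdges(truth) == 0)
        stop("truth network has no edges", call. = FALSE)
    key <- .edgeKey(net@edges$from, net@edges$to)
    truthKey <- .edgeKey(truth@edges$from, truth@edges$to)
    idx <- match(truthKey, key)
    w <- ifelse(is.na(idx), 0, net@edges$weight[idx])
    mean(abs(w - truth@edges$weight))
}
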