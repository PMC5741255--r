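#' Integration configuration
#'
#' Bundles the parameters of the entropy integration model: the imputation
#' weight `epsilon` given to edges absent from a source (and mirrored as
#' `1 - epsilon` for weight-1 edges, so binary entropy is defined), the
#' adjustment exponent `theta` of the confidence transform, and the inclusive
#' grid searched by [tuneTheta()]. Defaults: `epsilon = 0.001`,
#' `theta = 0.3`, grid 0.2 to 0.6 in steps of 0.01.
#'
#' @param epsilon imputation weight in (0, 0.5).
#' @param theta positive adjustment exponent.
#' @param thetaGrid strictly increasing positive numeric vector.
#' @return an [IntegrationConfig-class].
#' @export
integrationConfig <- function(epsilon = 0.001, theta = 0.3,
                              thetaGrid = seq(0.2, 0.6, by = 0.01)) {
    new("IntegrationConfig", epsilon = epsilon, theta = theta,
        thetaGrid = thetaGrid)
}

setMethod("show", "IntegrationConfig", function(object) {
    cat(sprintf("IntegrationConfig: epsilon = %g, theta = %g, grid [%g, %g] (%d points)\n",
                object@epsilon, object@theta, min(object@thetaGrid),
                max(object@thetaGrid), length(object@thetaGrid)))
})

#' Clip weights into the closed interval from epsilon to 1 - epsilon
#'
#' Maps a weight of 0 (edge absent from a source) to `epsilon` and a weight of
#' 1 to `1 - epsilon`, so the binary entropy of every entry is defined and
#' positive. Weights already inside the interval pass through unchanged;
#' values in `(0, epsilon)` or `(1 - epsilon, 1)` are pulled to the nearest
#' bound.
#'
#' @param w numeric vector of weights in `[0, 1]`.
#' @param epsilon imputation weight in (0, 0.5); default 0.001.
#' @return numeric vector in `[epsilon, 1 - epsilon]`.
#' @examples
#' clipWeights(c(0, 0.5, 1))  # 0.001 0.500 0.999
#' @export
clipWeights <- function(w, epsilon = 0.001) {
    .assertScalarNumeric(epsilon, "epsilon")
    if (epsilon <= 0 || epsilon >= 0.5)
        stop("'epsilon' must lie in (0, 0.5)", call. = FALSE)
    if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
        stop("weights must lie in [0, 1]", call. = FALSE)
    pmin(pmax(w, epsilon), 1 - epsilon)
}

#' Binary entropy of an edge-existence probability
#'
#' Treats a weight `w` as the probability that the edge exists and returns the
#' entropy of that Bernoulli variable, `-w log2(w) - (1-w) log2(1-w)`, in
#' bits. It is maximal (1 bit) at `w = 0.5` — the most uncertain edge — and
#' approaches 0 as `w` approaches 0 or 1. Endpoints are rejected: clip first
#' with [clipWeights()].
#'
#' @param w numeric vector strictly inside (0, 1).
#' @return entropy in bits, in `(0, 1]`.
#' @examples
#' binaryEntropy(0.5)   # 1
#' binaryEntropy(0.25)  # 0.8112781
#' @export
binaryEntropy <- function(w) {
    if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1))
        stop("binary entropy requires weights strictly inside (0, 1); ",
             "clip with clipWeights() first", call. = FALSE)
    -w * log2(w) - (1 - w) * log2(1 - w)
}

#' Confidence transform of entropy
#'
#' Converts the uncertainty of an edge into a source confidence:
#' `C = 1 - exp(-H^(-theta))`. The function is strictly decreasing in `H` and
#' confined to (0, 1): a source that is certain about an edge (small `H`,
#' weight near 0 or near 1) gets confidence near 1, while a maximally
#' uncertain source (`H = 1`) gets `1 - exp(-1)`. The exponent `theta`
#' controls how sharply uncertainty is penalized; for `theta > 1` the
#' transform saturates near 1 for small `H`, which is why tuning is confined
#' to the discriminating range `[0.2, 0.6]`.
#'
#' @param h entropy in bits, in `(0, 1]`.
#' @param theta positive adjustment exponent; default 0.3.
#' @return confidence values in (0, 1).
#' @examples
#' confidenceWeight(1, 0.3)  # 1 - exp(-1)
#' @export
confidenceWeight <- function(h, theta = 0.3) {
    .assertScalarNumeric(theta, "theta")
    if (theta <= 0) stop("'theta' must be positive", call. = FALSE)
    if (any(!is.finite(h)) || any(h <= 0) || any(h > 1))
        stop("entropy must lie in (0, 1]", call. = FALSE)
    1 - exp(-h^(-theta))
}

#' Per-edge integration parameters
#'
#' Given the m clipped component weights of one edge, computes the normalized
#' mixing coefficients alpha: each component's confidence (via
#' [binaryEntropy()] and [confidenceWeight()]) divided by the sum of all m
#' confidences. The coefficients are positive and sum to 1.
#'
#' @param w numeric vector of m >= 2 clipped weights, strictly inside (0, 1).
#' @param theta positive adjustment exponent; default 0.3.
#' @return numeric vector of m coefficients summing to 1.
#' @examples
#' integrationWeights(c(0.9, 0.5), theta = 0.3)
#' @export
integrationWeights <- function(w, theta = 0.3) {
    if (length(w) < 2)
        stop("integration requires at least 2 component weights", call. = FALSE)
    cw <- confidenceWeight(binaryEntropy(w), theta)
    cw / sum(cw)
}

#' Integrated weight of one edge
#'
#' The convex combination `sum(alpha_k * w_k)` of the m component weights with
#' the entropy-derived coefficients of [integrationWeights()]. The result
#' always lies between the smallest and largest component weight; a source
#' that confidently lacks the edge (imputed weight epsilon, low entropy) pulls
#' the integrated weight down.
#'
#' @inheritParams integrationWeights
#' @return a single weight in `[min(w), max(w)]`.
#' @examples
#' integrateEdge(c(0.9, 0.5), theta = 0.3)    # 0.712
#' integrateEdge(c(0.8, 0.001), theta = 0.3)  # 0.325
#' @export
integrateEdge <- function(w, theta = 0.3) {
    sum(integrationWeights(w, theta) * w)
}

#' Build the edge-union profile of m networks
#'
#' Combines the edges of all component networks into the union edge set and
#' records, per edge, the length-m vector of clipped weights: the source
#' weight where the edge exists (weights of exactly 1 become `1 - epsilon`),
#' `epsilon` where it is absent — including when one endpoint is entirely
#' missing from that source. Source order is preserved in `networkLabels`.
#'
#' @param nets list of m >= 2 [WeightedNetwork-class] objects with weights in
#'   `(0, 1]` (normalize first with [normalizeWeights()]).
#' @param epsilon imputation weight; default 0.001.
#' @return a [UnionProfile-class].
#' @export
buildUnion <- function(nets, epsilon = 0.001) {
    if (!is.list(nets) || length(nets) < 2)
        stop("integration requires at least 2 networks", call. = FALSE)
    if (!all(vapply(nets, is, TRUE, "WeightedNetwork")))
        stop("'nets' must be a list of WeightedNetwork objects", call. = FALSE)
    for (k in seq_along(nets)) {
        w <- nets[[k]]@edges$weight
        if (length(w) && max(w) > 1)
            stop("network ", k, " has weights > 1; run normalizeWeights() first",
                 call. = FALSE)
    }
    labels <- names(nets)
    if (is.null(labels) || any(!nzchar(labels)))
        labels <- paste0("net", seq_along(nets))
    keys <- lapply(nets, function(n) .edgeKey(n@edges$from, n@edges$to))
    unionKey <- sort(unique(unlist(keys)))
    ne <- length(unionKey)
    m <- length(nets)
    W <- matrix(epsilon, nrow = ne, ncol = m, dimnames = list(NULL, labels))
    obs <- matrix(FALSE, nrow = ne, ncol = m, dimnames = list(NULL, labels))
    for (k in seq_len(m)) {
        idx <- match(keys[[k]], unionKey)
        W[idx, k] <- clipWeights(nets[[k]]@edges$weight, epsilon)
        obs[idx, k] <- TRUE
    }
    parts <- strsplit(unionKey, "\t", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1L),
                        to = vapply(parts, `[`, "", 2L))
    allNodes <- sort(unique(unlist(lapply(nets, nodes))))
    new("UnionProfile", edges = edges, weights = W, observed = obs,
        networkLabels = labels, nodes = allNodes, epsilon = epsilon)
}

#' @rdname accessors
#' @export
setMethod("nodes", "UnionProfile", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "UnionProfile", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("numEdges", "UnionProfile", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("numNodes", "UnionProfile", function(x) length(x@nodes))

setMethod("show", "UnionProfile", function(object) {
    cat("UnionProfile:", nrow(object@edges), "union edges from",
        length(object@networkLabels), "networks (",
        paste(object@networkLabels, collapse = ", "), ")\n")
    cat(sprintf("  epsilon = %g; imputed entries: %d of %d\n", object@epsilon,
                sum(!object@observed), length(object@observed)))
})

# vectorized Eq-by-Eq rescoring of a union profile at one theta
.integrateProfile <- function(profile, theta) {
    W <- profile@weights
    H <- -W * log2(W) - (1 - W) * log2(1 - W)
    C <- 1 - exp(-H^(-theta))
    alpha <- C / rowSums(C)
    rowSums(alpha * W)
}

#' @describeIn integrateNetworks integrate a list of component networks.
#' @export
setMethod("integrateNetworks", "list", function(x, config = integrationConfig()) {
    stopifnot(is(config, "IntegrationConfig"))
    integrateNetworks(buildUnion(x, config@epsilon), config)
})

#' @describeIn integrateNetworks integrate a prebuilt union profile (used by
#'   the tuning loop to avoid rebuilding the union at every grid point).
#' @export
setMethod("integrateNetworks", "UnionProfile", function(x, config = integrationConfig()) {
    stopifnot(is(config, "IntegrationConfig"))
    w <- .integrateProfile(x, config@theta)
    new("WeightedNetwork", nodes = x@nodes,
        edges = data.frame(from = x@edges$from, to = x@edges$to, weight = w))
})
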