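#' Accessors for entnet classes
#'
#' Small accessor generics: node set, edge table, counts, weights and results.
#'
#' @param x an entnet object.
#' @return `nodes()` a character vector; `edgeTable()` a `data.frame`;
#'   `numNodes()`/`numEdges()` integer counts; `edgeWeights()` a numeric
#'   vector named by edge key; `geneSets()` a named list; `bestTheta()` a
#'   numeric scalar; `auc()` a numeric scalar; `pooledRecords()` and
#'   `rocPoints()` data frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("bestTheta", function(x) standardGeneric("bestTheta"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("pooledRecords", function(x) standardGeneric("pooledRecords"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' Integrate component networks into one rescored network
#'
#' @param x a list of [WeightedNetwork-class] objects (m >= 2, weights in
#'   `(0, 1]`) or a prebuilt [UnionProfile-class].
#' @param config an [IntegrationConfig-class]; defaults to
#'   [integrationConfig()].
#' @return a [WeightedNetwork-class] with exactly the union's nodes and edges
#'   and entropy-rescored weights.
#' @seealso [buildUnion()], [integrateEdge()]
#' @export
setGeneric("integrateNetworks",
    function(x, config = integrationConfig()) standardGeneric("integrateNetworks"))
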