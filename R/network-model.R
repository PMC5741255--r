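#' Canonical unordered gene pair
#'
#' Orders each gene pair so that the lexicographically smaller token comes
#' first; `canonicalEdge(a, b)` and `canonicalEdge(b, a)` are identical.
#' Self-pairs are rejected: the entropy model is defined on pairs of distinct
#' genes.
#'
#' @param a,b character vectors of gene identifiers (recycled to a common
#'   length).
#' @return `data.frame` with character columns `from` and `to`, `from < to`
#'   row-wise.
#' @examples
#' canonicalEdge("TP53", "BRCA1")
#' @export
canonicalEdge <- function(a, b) {
    a <- as.character(a); b <- as.character(b)
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    if (any(a == b))
        stop("self-loops are not allowed: ",
             paste(unique(a[a == b]), collapse = ", "), call. = FALSE)
    swap <- a > b
    data.frame(from = ifelse(swap, b, a), to = ifelse(swap, a, b))
}

# shared edge-table builder: canonicalizes, applies the self-loop and
# duplicate policies, reports what was dropped/collapsed
.buildEdges <- function(from, to, weight, quiet = TRUE) {
    keep <- from != to
    nSelf <- sum(!keep)
    if (nSelf > 0 && !quiet)
        message("dropped ", nSelf, " self-loop(s)")
    from <- from[keep]; to <- to[keep]; weight <- weight[keep]
    if (length(from)) {
        swap <- from > to
        tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
        key <- .edgeKey(from, to)
        if (anyDuplicated(key)) {
            nDup <- sum(duplicated(key))
            if (!quiet)
                message("collapsed ", nDup,
                        " duplicate edge record(s), keeping the maximum weight")
            w <- tapply(weight, key, max)
            key <- names(w)
            parts <- strsplit(key, "\t", fixed = TRUE)
            from <- vapply(parts, `[`, "", 1L)
            to <- vapply(parts, `[`, "", 2L)
            weight <- as.numeric(w)
        }
        o <- order(from, to)
        from <- from[o]; to <- to[o]; weight <- weight[o]
    }
    data.frame(from = from, to = to, weight = weight)
}

#' Construct a weighted network
#'
#' Builds a [WeightedNetwork-class] from parallel edge vectors. Edges are
#' canonicalized; self-loops are dropped and duplicate records (either
#' orientation) collapsed by keeping the maximum weight, the conservative
#' choice toward association evidence.
#'
#' @param from,to character vectors of gene identifiers.
#' @param weight positive numeric weights.
#' @param nodes optional extra nodes beyond the edge endpoints (isolated
#'   genes).
#' @param quiet suppress messages about dropped/collapsed records.
#' @return a [WeightedNetwork-class].
#' @examples
#' net <- weightedNetwork(c("a", "b"), c("b", "c"), c(0.5, 1))
#' numEdges(net)
#' @export
weightedNetwork <- function(from = character(), to = character(),
                            weight = numeric(), nodes = NULL, quiet = TRUE) {
    from <- as.character(from); to <- as.character(to)
    weight <- as.numeric(weight)
    if (length(from) != length(to) || length(from) != length(weight))
        stop("'from', 'to' and 'weight' must have equal length", call. = FALSE)
    ed <- .buildEdges(from, to, weight, quiet = quiet)
    allNodes <- sort(unique(c(ed$from, ed$to, as.character(nodes))))
    new("WeightedNetwork", nodes = allNodes, edges = ed)
}

#' @rdname accessors
#' @aliases nodes,WeightedNetwork-method
#' @export
setMethod("nodes", "WeightedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeTable", "WeightedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("numNodes", "WeightedNetwork", function(x) length(x@nodes))

#' @rdname accessors
#' @export
setMethod("numEdges", "WeightedNetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("edgeWeights", "WeightedNetwork", function(x) {
    w <- x@edges$weight
    names(w) <- .edgeKey(x@edges$from, x@edges$to)
    w
})

setMethod("show", "WeightedNetwork", function(object) {
    cat("WeightedNetwork with", numNodes(object), "nodes and",
        numEdges(object), "edges\n")
    if (numEdges(object) > 0) {
        w <- object@edges$weight
        cat(sprintf("  weight range: [%g, %g]\n", min(w), max(w)))
        print(utils::head(object@edges, 5L), row.names = FALSE)
        if (numEdges(object) > 5) cat("  ...\n")
    }
})

#' Read a weighted edge list
#'
#' Reads a tab-separated edge list (columns geneA, geneB, weight). Lines
#' starting with `#` are comments; a single header line is auto-detected by a
#' non-numeric third field. Self-loops are dropped and duplicate pairs in
#' either orientation are collapsed to the maximum weight, each with a
#' message. Weights are read as-is: normalization into `(0, 1]` is a separate
#' step ([normalizeWeights()]).
#'
#' @param path file path.
#' @param quiet suppress the dropped/collapsed messages.
#' @return a [WeightedNetwork-class].
#' @seealso [writeWeightedEdgeList()]
#' @export
readWeightedEdgeList <- function(path, quiet = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lineNo <- seq_along(lines)
    keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (length(lines) == 0) stop("empty edge-list file: ", path, call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop("line ", lineNo[which(nf < 3)[1]],
             ": expected at least 3 tab-separated fields", call. = FALSE)
    third <- vapply(fields, `[`, "", 3L)
    w <- suppressWarnings(as.numeric(third))
    # header: a single leading row whose weight field is not numeric
    if (is.na(w[1])) {
        if (length(lines) == 1)
            stop("empty edge-list file (header only): ", path, call. = FALSE)
        fields <- fields[-1]; w <- w[-1]; lineNo <- lineNo[-1]
    }
    if (anyNA(w))
        stop("line ", lineNo[which(is.na(w))[1]], ": non-numeric weight",
             call. = FALSE)
    if (any(w <= 0))
        stop("line ", lineNo[which(w <= 0)[1]], ": weight must be > 0",
             call. = FALSE)
    from <- vapply(fields, `[`, "", 1L)
    to <- vapply(fields, `[`, "", 2L)
    ed <- .buildEdges(from, to, w, quiet = quiet)
    allNodes <- sort(unique(c(from, to)))
    new("WeightedNetwork", nodes = allNodes, edges = ed)
}

#' Write a weighted edge list
#'
#' Writes one row per edge in canonical order with a fixed decimal precision,
#' preceded by a `geneA  geneB  weight` header. Reading the file back
#' reproduces the network with weights equal to the written precision.
#'
#' @param net a [WeightedNetwork-class].
#' @param path output file path.
#' @param digits decimal places for weights (default 6).
#' @return the path, invisibly.
#' @export
writeWeightedEdgeList <- function(net, path, digits = 6L) {
    stopifnot(is(net, "WeightedNetwork"))
    ed <- net@edges
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("geneA\tgeneB\tweight", con)
    if (nrow(ed) > 0)
        writeLines(sprintf("%s\t%s\t%.*f", ed$from, ed$to, digits, ed$weight),
                   con)
    invisible(path)
}

#' Normalize edge weights into (0, 1]
#'
#' Divides every weight by the network maximum, so ratios are preserved, the
#' largest weight becomes exactly 1 and all weights lie in `(0, 1]`.
#' Idempotent; a network without edges is returned unchanged.
#'
#' @param net a [WeightedNetwork-class] with positive weights.
#' @return the rescaled [WeightedNetwork-class].
#' @examples
#' net <- weightedNetwork(c("a", "b", "a"), c("b", "c", "c"), c(2, 4, 8))
#' edgeTable(normalizeWeights(net))$weight  # 0.25 0.50 1.00
#' @export
normalizeWeights <- function(net) {
    stopifnot(is(net, "WeightedNetwork"))
    ed <- net@edges
    if (nrow(ed) == 0) return(net)
    bad <- which(ed$weight <= 0)
    if (length(bad))
        stop("non-positive weight on edge ", ed$from[bad[1]], "--",
             ed$to[bad[1]], call. = FALSE)
    ed$weight <- ed$weight / max(ed$weight)
    initialize(net, edges = ed)
}

#' Construct a disease gene collection
#'
#' @param sets named list of character vectors of gene identifiers
#'   (duplicates within a set are collapsed).
#' @param descriptions optional named character vector of per-set
#'   descriptions.
#' @return a [DiseaseGeneCollection-class].
#' @export
diseaseGeneCollection <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("DiseaseGeneCollection", sets = sets,
        descriptions = descriptions[names(sets)])
}

#' @rdname accessors
#' @export
setMethod("geneSets", "DiseaseGeneCollection", function(x) x@sets)

#' Gene sets below the minimum seed size
#'
#' Labels of sets with fewer than `minSize` genes. Leave-one-out validation
#' requires at least 3 genes per set; smaller sets are kept in the collection
#' but flagged.
#'
#' @param x a [DiseaseGeneCollection-class].
#' @param minSize minimum usable set size (default 3).
#' @return character vector of set labels.
#' @export
flaggedSets <- function(x, minSize = 3L) {
    stopifnot(is(x, "DiseaseGeneCollection"))
    names(x@sets)[vapply(x@sets, length, 1L) < minSize]
}

setMethod("show", "DiseaseGeneCollection", function(object) {
    sizes <- vapply(object@sets, length, 1L)
    cat("DiseaseGeneCollection:", length(object@sets), "sets,",
        length(unique(unlist(object@sets))), "distinct genes\n")
    cat("  set sizes:", paste(range(sizes), collapse = "-"),
        "| flagged (<3 genes):", length(flaggedSets(object)), "\n")
})

#' Read GMT-style gene sets
#'
#' Each row is `label<TAB>description<TAB>gene1<TAB>...<TAB>geneN`. Duplicate
#' genes within a set are collapsed; sets with fewer than 3 genes are retained
#' and can be listed with [flaggedSets()].
#'
#' @param path GMT file path.
#' @return a [DiseaseGeneCollection-class].
#' @export
readGeneSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lineNo <- seq_along(lines)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]; lineNo <- lineNo[keep]
    if (length(lines) == 0) stop("empty gene-set file: ", path, call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3))
        stop("line ", lineNo[which(nf < 3)[1]],
             ": expected label, description and at least one gene",
             call. = FALSE)
    labels <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(labels))
        stop("duplicated set label: ", labels[duplicated(labels)][1],
             call. = FALSE)
    descriptions <- vapply(fields, `[`, "", 2L)
    sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
    names(sets) <- labels
    names(descriptions) <- labels
    bad <- which(lengths(sets) == 0)
    if (length(bad))
        stop("line ", lineNo[bad[1]], ": set '", labels[bad[1]],
             "' has no genes", call. = FALSE)
    new("DiseaseGeneCollection", sets = sets, descriptions = descriptions)
}

#' Write GMT-style gene sets
#'
#' @param collection a [DiseaseGeneCollection-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGeneSets <- function(collection, path) {
    stopifnot(is(collection, "DiseaseGeneCollection"))
    rows <- vapply(names(collection@sets), function(lab) {
        paste(c(lab, collection@descriptions[[lab]],
                collection@sets[[lab]]), collapse = "\t")
    }, "")
    writeLines(rows, path)
    invisible(path)
}
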