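#' Specification of a synthetic network fixture
#'
#' Parameters under which the generators emulate a compendium of gene
#' association sources: one latent weighted network is the truth, and each of
#' `mNetworks` observed sources is an incomplete (edges dropped with
#' probability `missingness`) and noisy (additive Gaussian perturbation with
#' standard deviation `observationNoise`, re-clipped into `(0, 1]`) view of
#' it.
#'
#' Defaults describe a small but structured compendium: 50 genes, 4 sources,
#' edge density 0.1, half the latent edges missing from any given source, and
#' noise of 0.15 weight units — enough disagreement that shared-edge weight
#' correlations between sources are modest, as they are between real
#' association databases.
#'
#' @param nGenes number of genes (>= 4); default 50.
#' @param mNetworks number of observed sources (>= 2); default 4.
#' @param edgeDensity latent edge probability per gene pair; default 0.1.
#' @param observationNoise noise standard deviation (weight units); default
#'   0.15.
#' @param missingness per-source edge dropout probability; default 0.5.
#' @param seed master random seed; default 1.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(nGenes = 50L, mNetworks = 4L, edgeDensity = 0.1,
                        observationNoise = 0.15, missingness = 0.5,
                        seed = 1L) {
    new("FixtureSpec", nGenes = as.integer(nGenes),
        mNetworks = as.integer(mNetworks), edgeDensity = edgeDensity,
        observationNoise = observationNoise, missingness = missingness,
        seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf(paste0("FixtureSpec: %d genes, %d sources, density %g, ",
                       "noise sd %g, missingness %g, seed %d\n"),
                object@nGenes, object@mNetworks, object@edgeDensity,
                object@observationNoise, object@missingness, object@seed))
})

.geneNames <- function(n) sprintf("g%04d", seq_len(n))

# lower bound used when re-clipping noisy weights into (0, 1]
.weightFloor <- 0.001

#' Generate a latent network and its observed component networks
#'
#' Samples a latent network (each gene pair carries an edge with probability
#' `edgeDensity`, weights uniform in (0, 1]) and m observed sources: each
#' source drops every latent edge independently with probability
#' `missingness` and perturbs surviving weights with additive Gaussian noise,
#' re-clipped into `(0, 1]` (floor 0.001). Every network keeps the full gene
#' set as nodes. Fully reproducible from the spec's seed; each source draws
#' from its own child seed so adding a source never perturbs earlier ones.
#'
#' @param spec a [FixtureSpec-class].
#' @return list with elements `latent` (a [WeightedNetwork-class]) and
#'   `observed` (named list of m [WeightedNetwork-class] objects).
#' @export
generateComponentNetworks <- function(spec) {
    stopifnot(is(spec, "FixtureSpec"))
    validObject(spec)
    genes <- .geneNames(spec@nGenes)
    pairs <- utils::combn(genes, 2L)
    latent <- .withSeed(spec@seed, {
        on <- stats::runif(ncol(pairs)) < spec@edgeDensity
        w <- stats::runif(sum(on))
        weightedNetwork(pairs[1L, on], pairs[2L, on], pmax(w, .weightFloor),
                        nodes = genes)
    })
    le <- latent@edges
    observed <- lapply(seq_len(spec@mNetworks), function(k) {
        .withSeed(.childSeed(spec@seed, k), {
            keep <- stats::runif(nrow(le)) >= spec@missingness
            w <- le$weight[keep]
            if (spec@observationNoise > 0)
                w <- w + stats::rnorm(length(w), sd = spec@observationNoise)
            w <- pmin(pmax(w, .weightFloor), 1)
            weightedNetwork(le$from[keep], le$to[keep], w, nodes = genes)
        })
    })
    names(observed) <- paste0("source", seq_len(spec@mNetworks))
    list(latent = latent, observed = observed)
}

#' Generate a GO-like reference network
#'
#' Builds a surrogate of a shared-annotation-term reference: a random subset
#' of the latent edges receives an integer shared-term count of at least 3
#' that increases stochastically with the latent weight
#' (`3 + Binomial(maxTerms - 3, w)`), and counts are then normalized by their
#' maximum into `(0, 1]`. Reference weights therefore correlate positively
#' with the latent weights, as functional-similarity weights do with true
#' association strength.
#'
#' @param latent the latent [WeightedNetwork-class].
#' @param maxTerms largest possible shared-term count (>= 3); default 10.
#' @param coverage fraction of latent edges annotated in the reference;
#'   default 0.6.
#' @param seed random seed; default 1.
#' @return a [WeightedNetwork-class] reference.
#' @export
generateReferenceNetwork <- function(latent, maxTerms = 10L, coverage = 0.6,
                                     seed = 1L) {
    stopifnot(is(latent, "WeightedNetwork"))
    if (maxTerms < 3) stop("'maxTerms' must be >= 3", call. = FALSE)
    if (numEdges(latent) < 2)
        stop("latent network needs at least 2 edges", call. = FALSE)
    le <- latent@edges
    .withSeed(seed, {
        keep <- stats::runif(nrow(le)) < coverage
        if (sum(keep) < 2) keep[seq_len(2L)] <- TRUE
        counts <- 3 + stats::rbinom(sum(keep), size = as.integer(maxTerms) - 3L,
                                    prob = le$weight[keep])
        net <- weightedNetwork(le$from[keep], le$to[keep], counts,
                               nodes = latent@nodes)
        normalizeWeights(net)
    })
}

#' Plant high-weight disease modules
#'
#' Selects disjoint modules of `genesPer` genes and raises every
#' within-module edge weight by `boost` (capped at 1), creating missing
#' within-module edges at weight `boost`. Returns the modified network plus
#' the corresponding disease gene collection — a fixture in which disease
#' genes cluster, as they do in real gene association networks. With
#' `boost = 0` the network is returned unchanged (and no edges are added),
#' but the collection is still produced.
#'
#' @param latent a [WeightedNetwork-class].
#' @param nDiseases number of disease modules.
#' @param genesPer genes per module (>= 3, the minimum usable seed-set size).
#' @param boost weight increment in `[0, 1]`; default 0.8.
#' @param seed random seed; default 1.
#' @return list with elements `network` ([WeightedNetwork-class]) and
#'   `collection` ([DiseaseGeneCollection-class]).
#' @export
plantDiseaseModules <- function(latent, nDiseases, genesPer, boost = 0.8,
                                seed = 1L) {
    stopifnot(is(latent, "WeightedNetwork"))
    if (genesPer < 3) stop("'genesPer' must be >= 3", call. = FALSE)
    if (boost < 0 || boost > 1) stop("'boost' must lie in [0, 1]", call. = FALSE)
    nNeeded <- nDiseases * genesPer
    if (nNeeded > numNodes(latent))
        stop("not enough genes: need ", nNeeded, ", have ", numNodes(latent),
             call. = FALSE)
    .withSeed(seed, {
        chosen <- sample(nodes(latent), nNeeded)
        modules <- split(chosen, rep(seq_len(nDiseases), each = genesPer))
        names(modules) <- sprintf("disease%03d", seq_len(nDiseases))
        net <- latent
        if (boost > 0) {
            ed <- net@edges
            key <- .edgeKey(ed$from, ed$to)
            for (mod in modules) {
                pairs <- utils::combn(sort(mod), 2L)
                pk <- .edgeKey(pairs[1L, ], pairs[2L, ])
                idx <- match(pk, key)
                hit <- !is.na(idx)
                ed$weight[idx[hit]] <- pmin(1, ed$weight[idx[hit]] + boost)
                if (any(!hit)) {
                    ed <- rbind(ed, data.frame(from = pairs[1L, !hit],
                                               to = pairs[2L, !hit],
                                               weight = boost))
                    key <- .edgeKey(ed$from, ed$to)
                }
            }
            ed <- ed[order(ed$from, ed$to), , drop = FALSE]
            rownames(ed) <- NULL
            net <- new("WeightedNetwork", nodes = latent@nodes, edges = ed)
        }
        list(network = net, collection = diseaseGeneCollection(modules))
    })
}
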