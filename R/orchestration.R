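#' Run the full integration pipeline on edge-list files
#'
#' Reads the component networks, normalizes their weights into `(0, 1]`,
#' builds the edge union, rescores every union edge with the entropy model and
#' writes the integrated network plus a provenance record (source files,
#' epsilon, theta, node/edge counts) so every output is reproducible from its
#' parameters. Reruns on identical inputs produce byte-identical files.
#'
#' @param networkFiles character vector of >= 2 edge-list TSV paths.
#' @param outDir output directory (created if absent).
#' @param config an [IntegrationConfig-class].
#' @param normalize normalize source weights before integration (default
#'   TRUE).
#' @return invisibly, a list with the integrated [WeightedNetwork-class] and
#'   the two output paths.
#' @export
runIntegrate <- function(networkFiles, outDir,
                         config = integrationConfig(), normalize = TRUE) {
    if (length(networkFiles) < 2)
        stop("integration requires at least 2 network files", call. = FALSE)
    missing <- networkFiles[!file.exists(networkFiles)]
    if (length(missing))
        stop("input file(s) not found: ", paste(missing, collapse = ", "),
             call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    nets <- lapply(networkFiles, readWeightedEdgeList, quiet = TRUE)
    names(nets) <- basename(networkFiles)
    if (normalize) nets <- lapply(nets, normalizeWeights)
    profile <- buildUnion(nets, config@epsilon)
    integrated <- integrateNetworks(profile, config)
    netPath <- file.path(outDir, "integrated_network.tsv")
    writeWeightedEdgeList(integrated, netPath)
    provenance <- list(
        sources = as.list(setNames(as.character(networkFiles), names(nets))),
        epsilon = config@epsilon,
        theta = config@theta,
        normalized = normalize,
        union = list(nodes = numNodes(profile), edges = numEdges(profile)),
        output = list(nodes = numNodes(integrated),
                      edges = numEdges(integrated)))
    provPath <- file.path(outDir, "provenance.json")
    jsonlite::write_json(provenance, provPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(network = integrated, networkPath = netPath,
                   provenancePath = provPath))
}

#' Evaluate a background network for disease gene prediction
#'
#' Runs leave-one-out cross-validation (given a GMT gene-set file) or
#' new-gene prediction (given seed and test gene lists) on a background
#' network, and writes the pooled ranks, the top-k recovery curve, the ROC
#' points and an AUC report as CSV files.
#'
#' @param networkFile background network edge-list TSV.
#' @param outDir output directory (created if absent).
#' @param geneSetFile GMT file of disease gene sets (LOOCV mode).
#' @param seedFile,testFile plain-text gene lists, one gene per line
#'   (prediction mode); both required together.
#' @param kmax top-k window (default 100).
#' @return invisibly, a list with the [PooledRanks-class], the
#'   [RocCurve-class] and the output paths.
#' @export
runEvaluate <- function(networkFile, outDir, geneSetFile = NULL,
                        seedFile = NULL, testFile = NULL, kmax = 100L) {
    if (!file.exists(networkFile))
        stop("network file not found: ", networkFile, call. = FALSE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    net <- readWeightedEdgeList(networkFile, quiet = TRUE)
    if (!is.null(geneSetFile)) {
        collection <- readGeneSets(geneSetFile)
        pooled <- leaveOneOut(net, collection)
    } else if (!is.null(seedFile) && !is.null(testFile)) {
        seeds <- readLines(seedFile, warn = FALSE)
        tests <- readLines(testFile, warn = FALSE)
        pooled <- predictNewGenes(net, seeds[nzchar(seeds)],
                                  tests[nzchar(tests)])
    } else {
        stop("provide either 'geneSetFile' (LOOCV) or both 'seedFile' and ",
             "'testFile' (prediction)", call. = FALSE)
    }
    roc <- rocCurve(pooled)
    topk <- topkCurve(pooled, kmax)
    paths <- c(ranks = file.path(outDir, "pooled_ranks.csv"),
               topk = file.path(outDir, "topk_curve.csv"),
               roc = file.path(outDir, "roc_points.csv"),
               auc = file.path(outDir, "auc_report.csv"))
    utils::write.csv(pooledRecords(pooled), paths[["ranks"]],
                     row.names = FALSE)
    utils::write.csv(topk, paths[["topk"]], row.names = FALSE)
    utils::write.csv(rocPoints(roc), paths[["roc"]], row.names = FALSE)
    utils::write.csv(data.frame(nCases = nrow(pooledRecords(pooled)),
                                auc = auc(roc)),
                     paths[["auc"]], row.names = FALSE)
    invisible(list(pooled = pooled, roc = roc, paths = paths))
}

#' Write a complete synthetic study to disk
#'
#' Generates the latent truth, the observed component networks, a GO-like
#' reference and planted disease gene sets from one [FixtureSpec-class], and
#' writes them in the standard TSV/GMT formats — everything the integrate,
#' tune, compare and evaluate stages need, with no external downloads.
#'
#' @param spec a [FixtureSpec-class].
#' @param outDir output directory (created if absent).
#' @param nDiseases,genesPer,boost module-planting parameters passed to
#'   [plantDiseaseModules()].
#' @return invisibly, the named vector of written paths.
#' @export
runSimulate <- function(spec, outDir, nDiseases = 5L, genesPer = 4L,
                        boost = 0.8) {
    stopifnot(is(spec, "FixtureSpec"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    comp <- generateComponentNetworks(spec)
    reference <- generateReferenceNetwork(comp$latent,
                                          seed = .childSeed(spec@seed, 1001L))
    planted <- plantDiseaseModules(comp$latent, nDiseases, genesPer, boost,
                                   seed = .childSeed(spec@seed, 1002L))
    paths <- c(latent = file.path(outDir, "latent_network.tsv"),
               reference = file.path(outDir, "reference_network.tsv"),
               planted = file.path(outDir, "planted_network.tsv"),
               geneSets = file.path(outDir, "disease_gene_sets.gmt"))
    writeWeightedEdgeList(comp$latent, paths[["latent"]])
    writeWeightedEdgeList(reference, paths[["reference"]])
    writeWeightedEdgeList(planted$network, paths[["planted"]])
    writeGeneSets(planted$collection, paths[["geneSets"]])
    for (k in seq_along(comp$observed)) {
        p <- file.path(outDir, sprintf("source%02d.tsv", k))
        writeWeightedEdgeList(comp$observed[[k]], p)
        paths[[sprintf("source%02d", k)]] <- p
    }
    invisible(paths)
}
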