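# Independent oracles and small fixture builders. Everything here is written
# as plain scalar arithmetic or calls to unrelated stats routines, never to
# the package's own vectorized paths.

# random canonical network over n genes; weights uniform in (0, 1]
randomNetwork <- function(n, density = 0.4, seed = 1, genes = NULL) {
    set.seed(seed)
    if (is.null(genes)) genes <- sprintf("n%03d", seq_len(n))
    pairs <- combn(genes, 2)
    on <- runif(ncol(pairs)) < density
    if (!any(on)) on[1] <- TRUE
    weightedNetwork(pairs[1, on], pairs[2, on],
                    pmax(runif(sum(on)), 1e-3), nodes = genes)
}

# scalar per-edge evaluation of the entropy rescoring chain:
# clip -> binary entropy -> confidence -> normalize -> convex combination
oracleIntegrateVector <- function(w, theta, eps = 0.001) {
    cw <- numeric(length(w))
    for (k in seq_along(w)) {
        wk <- w[k]
        if (wk < eps) wk <- eps
        if (wk > 1 - eps) wk <- 1 - eps
        h <- -wk * log2(wk) - (1 - wk) * log2(1 - wk)
        cw[k] <- 1 - exp(-h^(-theta))
    }
    s <- 0
    for (k in seq_along(w)) {
        wk <- min(max(w[k], eps), 1 - eps)
        s <- s + cw[k] / sum(cw) * wk
    }
    s
}

# brute-force integration of a list of networks: loop over the union edges,
# look each weight up in each source (0 when absent), evaluate the scalar
# chain
oracleIntegrateNetworks <- function(nets, theta = 0.3, eps = 0.001) {
    keys <- unique(unlist(lapply(nets, function(n) {
        e <- edgeTable(n)
        paste(e$from, e$to)
    })))
    keys <- sort(keys)
    maps <- lapply(nets, function(n) {
        e <- edgeTable(n)
        setNames(e$weight, paste(e$from, e$to))
    })
    out <- numeric(length(keys))
    for (i in seq_along(keys)) {
        w <- vapply(maps, function(mp) {
            if (keys[i] %in% names(mp)) mp[[keys[i]]] else 0
        }, 0)
        out[i] <- oracleIntegrateVector(w, theta, eps)
    }
    setNames(out, keys)
}

# Mann-Whitney AUC of one positive at rank r among n candidates:
# the fraction of the n - 1 negatives ranked strictly below the positive
oracleCaseAuc <- function(r, n) (n - r) / (n - 1)

# rank-sum AUC from raw scores of one positive against negatives
oracleRankSumAuc <- function(posScore, negScores) {
    w <- wilcox.test(posScore, negScores, exact = FALSE)$statistic
    unname(w) / (length(posScore) * length(negScores))
}

# exhaustive threshold-sweep ROC for pooled records: evaluates FPR/TPR at
# every attainable per-case cutoff (plus the pre-rank points) by direct
# counting, then integrates trapezoidally
oracleRocAuc <- function(rank, n) {
    thr <- sort(unique(c(0, 1, as.vector(vapply(seq_along(rank), function(i)
        c((rank[i] - 1) / n[i], rank[i] / n[i]), c(0, 0))),
        unlist(lapply(seq_along(rank), function(i) seq_len(n[i]) / n[i])))))
    tpr <- fpr <- numeric(length(thr))
    for (j in seq_along(thr)) {
        hits <- negs <- 0
        for (i in seq_along(rank)) {
            k <- floor(thr[j] * n[i] + 1e-9)
            hit <- rank[i] <= k
            hits <- hits + hit
            negs <- negs + (k - hit) / (n[i] - 1)
        }
        tpr[j] <- hits / length(rank)
        fpr[j] <- negs / length(rank)
    }
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

makePooled <- function(rank, n, set = "s", gene = NULL) {
    if (is.null(gene)) gene <- sprintf("t%03d", seq_along(rank))
    new("PooledRanks",
        records = data.frame(set = set, gene = gene, rank = rank,
                             nCandidates = n))
}
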