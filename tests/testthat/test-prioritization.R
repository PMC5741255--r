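test_that("neighborhood scores sum seed-link weights and default to zero", {
    net <- weightedNetwork(c("s1", "s2", "x", "s1"), c("g1", "g1", "y", "s2"),
                           c(0.3, 0.4, 0.9, 0.2))
    sc <- neighborhoodScores(net, c("s1", "s2"))
    expect_equal(sc[["g1"]], 0.7)
    expect_equal(sc[["x"]], 0)   # no link to any seed
    expect_equal(sc[["y"]], 0)
    expect_false(any(c("s1", "s2") %in% names(sc)))
    expect_warning(neighborhoodScores(net, c("s1", "absent")), "absent")
    expect_error(suppressWarnings(neighborhoodScores(net, "absent")),
                 "no seed gene")
})

test_that("neighborhood scores match a per-gene brute-force sum on a fixture", {
    net <- randomNetwork(20, density = 0.3, seed = 4)
    seeds <- nodes(net)[c(2, 7, 11)]
    sc <- neighborhoodScores(net, seeds)
    ed <- edgeTable(net)
    for (g in setdiff(nodes(net), seeds)) {
        s <- 0
        for (i in seq_len(nrow(ed))) {
            if (ed$from[i] == g && ed$to[i] %in% seeds) s <- s + ed$weight[i]
            if (ed$to[i] == g && ed$from[i] %in% seeds) s <- s + ed$weight[i]
        }
        expect_equal(sc[[g]], s)
    }
})

test_that("candidates are ranked descending with worst-rank ties", {
    rl <- rankCandidates(c(a = 0.9, b = 0.5, c = 0.5, d = 0.1))
    e <- rankedEntries(rl)
    expect_equal(e$gene, c("a", "b", "c", "d"))
    expect_equal(e$rank, c(1, 3, 3, 4))
    # degenerate all-zero plateau: everyone shares the worst rank
    z <- rankCandidates(c(q = 0, p = 0, r = 0))
    expect_equal(rankedEntries(z)$rank, c(3, 3, 3))
    expect_equal(rankedEntries(z)$gene, c("p", "q", "r"))  # alphabetical listing
    expect_error(rankCandidates(c(a = 1), seeds = "a"), "seed")
    # random fixture: agree with an independent sort-and-scan
    set.seed(31)
    sc <- setNames(round(runif(30), 2), sprintf("c%02d", 1:30))
    e <- rankedEntries(rankCandidates(sc))
    for (i in seq_len(nrow(e)))
        expect_equal(e$rank[i], sum(sc > sc[[e$gene[i]]]) + sum(sc == sc[[e$gene[i]]]))
})

test_that("leave-one-out ranks a held-out gene linked to the seeds first", {
    # 5-node toy: a--b and a--c carry weight 0.9, nothing else is connected
    net <- weightedNetwork(c("a", "a"), c("b", "c"), c(0.9, 0.9),
                           nodes = c("a", "b", "c", "d", "e"))
    coll <- diseaseGeneCollection(list(D = c("a", "b", "c")))
    pooled <- leaveOneOut(net, coll)
    rec <- pooledRecords(pooled)
    expect_equal(nrow(rec), 3)
    expect_equal(rec$rank[rec$gene == "b"], 1)  # b links seed a; d, e score 0
    expect_equal(rec$rank[rec$gene == "c"], 1)
    expect_equal(unique(rec$nCandidates), 3)
})

test_that("leave-one-out skips small sets and absent genes per the >=3 rule", {
    net <- randomNetwork(15, density = 0.4, seed = 12)
    g <- nodes(net)
    coll <- diseaseGeneCollection(list(
        ok = g[1:4],
        tiny = g[5:6],                       # < 3 genes: skipped
        partial = c(g[7:9], "missing_gene")  # absent member skipped, rest tested
    ))
    expect_warning(pooled <- leaveOneOut(net, coll), "skipped")
    rec <- pooledRecords(pooled)
    expect_equal(sum(rec$set == "ok"), 4)
    expect_equal(sum(rec$set == "tiny"), 0)
    expect_equal(sum(rec$set == "partial"), 3)
    expect_true(all(rec$rank >= 1 & rec$rank <= rec$nCandidates))
    empty <- diseaseGeneCollection(list(tiny = g[1:2]))
    expect_error(suppressWarnings(leaveOneOut(net, empty)), "no usable")
})

test_that("planted disease modules rank far better than permuted labels", {
    spec <- fixtureSpec(nGenes = 60, seed = 202)
    comp <- generateComponentNetworks(spec)
    planted <- plantDiseaseModules(comp$latent, nDiseases = 4, genesPer = 8,
                                   boost = 0.8, seed = 7)
    pooled <- leaveOneOut(planted$network, planted$collection)
    medPlanted <- median(pooledRecords(pooled)$rank)
    # permuted labels: same set sizes, random genes
    set.seed(99)
    fake <- diseaseGeneCollection(split(sample(nodes(planted$network), 32),
                                        rep(1:4, each = 8)))
    pooledPerm <- leaveOneOut(planted$network, fake)
    medPerm <- median(pooledRecords(pooledPerm)$rank)
    expect_lt(medPlanted, medPerm / 4)
})

test_that("new-gene prediction enforces disjoint seeds and records test ranks", {
    net <- randomNetwork(20, density = 0.4, seed = 44)
    g <- nodes(net)
    expect_error(predictNewGenes(net, g[1:3], g[3:5]), "disjoint")
    expect_warning(
        pooled <- predictNewGenes(net, g[1:3], c(g[4:8], "not_in_net")),
        "absent")
    rec <- pooledRecords(pooled)
    expect_equal(nrow(rec), 5)
    expect_equal(unique(rec$nCandidates), 17)  # 20 nodes - 3 seeds
    expect_true(all(rec$gene %in% g[4:8]))
})

test_that("obesity-scale prediction beats permuted seed labels", {
    # 24 seeds, 367 test genes, planted associations: mean test rank must beat
    # a label permutation on the same network
    spec <- fixtureSpec(nGenes = 500, mNetworks = 2, edgeDensity = 0.02,
                        seed = 77)
    comp <- generateComponentNetworks(spec)
    planted <- plantDiseaseModules(comp$latent, nDiseases = 1, genesPer = 100,
                                   boost = 0.5, seed = 8)
    module <- geneSets(planted$collection)[[1]]
    seeds <- module[1:24]
    testGenes <- module[25:100]
    pooled <- predictNewGenes(planted$network, seeds, testGenes)
    set.seed(123)
    randomTests <- sample(setdiff(nodes(planted$network), c(seeds, module)), 76)
    pooledPerm <- predictNewGenes(planted$network, seeds, randomTests)
    expect_lt(mean(pooledRecords(pooled)$rank),
              mean(pooledRecords(pooledPerm)$rank))
})

test_that("top-k curve counts pooled ranks within each cutoff", {
    expect_equal(topkCurve(makePooled(c(1, 1, 1), c(50, 50, 50)))$percent,
                 c(0, rep(100, 100)))
    expect_equal(unique(topkCurve(makePooled(c(150, 200), c(300, 300)))$percent), 0)
    tk <- topkCurve(makePooled(c(1, 50, 200), c(300, 300, 300)))
    expect_equal(tk$percent[tk$k == 1], 100 / 3, tolerance = 1e-9)
    expect_equal(tk$percent[tk$k == 49], 100 / 3, tolerance = 1e-9)
    expect_equal(tk$percent[tk$k == 50], 200 / 3, tolerance = 1e-9)
    expect_equal(tk$percent[tk$k == 100], 200 / 3, tolerance = 1e-9)
    expect_true(all(diff(tk$percent) >= 0))
})

test_that("ROC curve is monotone with exact endpoints and oracle-equal AUC", {
    pooled <- makePooled(c(1, 3), c(5, 5))
    roc <- rocCurve(pooled)
    pts <- rocPoints(roc)
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
    expect_equal(auc(roc), oracleRocAuc(c(1, 3), c(5, 5)), tolerance = 1e-12)
    # mean of the per-case Mann-Whitney areas for equal pool sizes
    expect_equal(auc(roc), mean(c(oracleCaseAuc(1, 5), oracleCaseAuc(3, 5))),
                 tolerance = 1e-12)
})

test_that("single-case ROC equals the rank-sum AUC on score fixtures", {
    set.seed(55)
    for (i in 1:10) {
        n <- sample(10:50, 1)
        scores <- runif(n)
        pos <- sample(n, 1)
        r <- sum(scores > scores[pos]) + sum(scores == scores[pos])
        pooled <- makePooled(r, n)
        expect_equal(auc(rocCurve(pooled)),
                     oracleRankSumAuc(scores[pos], scores[-pos]),
                     tolerance = 1e-9)
    }
})

test_that("perfect rankings drive AUC toward one", {
    roc <- rocCurve(makePooled(rep(1, 20), rep(2000, 20)))
    expect_gt(auc(roc), 0.999)
    expect_lte(auc(roc), 1)
})

test_that("uniformly random ranks give AUC near one half", {
    set.seed(321)
    aucs <- replicate(200, {
        n <- 500
        r <- sample(n, 25, replace = TRUE)
        auc(rocCurve(makePooled(r, rep(n, 25))))
    })
    expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("planted-module AUC beats permuted labels in paired replicates", {
    wins <- 0
    for (s in 1:20) {
        spec <- fixtureSpec(nGenes = 40, mNetworks = 2, seed = 400 + s)
        comp <- generateComponentNetworks(spec)
        planted <- plantDiseaseModules(comp$latent, nDiseases = 2, genesPer = 6,
                                       boost = 0.8, seed = s)
        a1 <- auc(rocCurve(leaveOneOut(planted$network, planted$collection)))
        set.seed(500 + s)
        fake <- diseaseGeneCollection(split(sample(nodes(planted$network), 12),
                                            rep(1:2, each = 6)))
        a0 <- auc(rocCurve(suppressWarnings(leaveOneOut(planted$network, fake))))
        wins <- wins + (a1 > a0)
    }
    expect_gte(wins, 19)
})
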