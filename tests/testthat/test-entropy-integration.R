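test_that("clipping maps absent and certain edges into [eps, 1 - eps]", {
    expect_equal(clipWeights(0, 0.001), 0.001)
    expect_equal(clipWeights(1, 0.001), 0.999)
    expect_equal(clipWeights(0.5, 0.001), 0.5)
    expect_equal(clipWeights(c(0.0005, 0.9995), 0.001), c(0.001, 0.999))
    expect_error(clipWeights(1.2), "\\[0, 1\\]")
    expect_error(clipWeights(0.5, epsilon = 0.7), "0, 0.5")
})

test_that("binary entropy matches the closed form and is symmetric", {
    expect_equal(binaryEntropy(0.5), 1)
    expect_equal(binaryEntropy(0.25), 0.811278, tolerance = 1e-6)
    expect_equal(binaryEntropy(0.001), 0.011408, tolerance = 1e-4)
    expect_error(binaryEntropy(0), "clip")
    expect_error(binaryEntropy(1), "clip")
    w <- seq(0.01, 0.99, by = 0.014)
    expect_equal(binaryEntropy(w), binaryEntropy(1 - w), tolerance = 1e-12)
    expect_true(all(binaryEntropy(w) > 0 & binaryEntropy(w) <= 1))
})

test_that("confidence transform has the stated value, range and monotonicity", {
    expect_equal(confidenceWeight(1, 0.3), 1 - exp(-1))
    expect_equal(confidenceWeight(0.5, 0.3), 0.7080417, tolerance = 1e-6)
    expect_gt(confidenceWeight(0.05, 0.3), confidenceWeight(0.5, 0.3))
    expect_error(confidenceWeight(0, 0.3), "\\(0, 1\\]")
    expect_error(confidenceWeight(0.5, -1), "positive")
    # strictly decreasing in h across the tuning range of theta
    h <- seq(0.005, 1, length.out = 200)
    for (theta in seq(0.2, 0.6, by = 0.1)) {
        cw <- confidenceWeight(h, theta)
        expect_true(all(diff(cw) < 0))
        expect_true(all(cw > 0 & cw < 1))
    }
})

test_that("integration weights are symmetric, normalized and match the oracle", {
    expect_equal(integrationWeights(rep(0.4, 4), 0.45), rep(0.25, 4))
    a <- integrationWeights(c(0.9, 0.5), 0.3)
    expect_equal(a, c(0.5307369, 0.4692631), tolerance = 1e-6)
    expect_error(integrationWeights(0.4), "at least 2")
    set.seed(3)
    for (i in 1:50) {
        m <- sample(2:5, 1)
        w <- runif(m, 0.001, 0.999)
        theta <- runif(1, 0.2, 0.6)
        a <- integrationWeights(w, theta)
        expect_equal(sum(a), 1, tolerance = 1e-12)
        expect_true(all(a > 0))
    }
})

test_that("per-edge integration matches the scalar oracle and stays convex", {
    expect_equal(integrateEdge(c(0.7, 0.7, 0.7), 0.5), 0.7)
    expect_equal(integrateEdge(c(0.9, 0.5), 0.3),
                 oracleIntegrateVector(c(0.9, 0.5), 0.3), tolerance = 1e-12)
    expect_equal(integrateEdge(c(0.8, 0.001), 0.3), 0.3252227,
                 tolerance = 1e-6)
    set.seed(5)
    for (i in 1:50) {
        w <- runif(sample(2:5, 1), 0.001, 0.999)
        theta <- runif(1, 0.2, 0.6)
        v <- integrateEdge(w, theta)
        expect_gte(v, min(w) - 1e-12)
        expect_lte(v, max(w) + 1e-12)
        expect_equal(v, oracleIntegrateVector(w, theta), tolerance = 1e-12)
    }
})

test_that("the union profile imputes epsilon exactly where edges are absent", {
    n1 <- weightedNetwork(c("a", "b"), c("b", "c"), c(0.8, 0.6))
    n2 <- weightedNetwork(c("b", "c"), c("c", "d"), c(0.5, 1))
    p <- buildUnion(list(n1, n2), epsilon = 0.001)
    expect_equal(numEdges(p), 3)
    expect_equal(nodes(p), c("a", "b", "c", "d"))
    key <- paste(edgeTable(p)$from, edgeTable(p)$to)
    W <- p@weights
    expect_equal(unname(W[key == "a b", ]), c(0.8, 0.001))
    expect_equal(unname(W[key == "b c", ]), c(0.6, 0.5))
    expect_equal(unname(W[key == "c d", ]), c(0.001, 0.999))  # weight 1 clipped
    expect_true(all(rowSums(p@observed) >= 1))
    # identical networks: no imputation anywhere
    p2 <- buildUnion(list(n1, n1))
    expect_true(all(p2@observed))
    expect_error(buildUnion(list(n1)), "at least 2")
    raw <- weightedNetwork("a", "b", 2)
    expect_error(buildUnion(list(n1, raw)), "normalizeWeights")
})

test_that("union edge counts follow inclusion-exclusion on planted overlap", {
    genes <- sprintf("u%03d", 1:40)
    pairs <- combn(genes, 2)
    set.seed(9)
    idx <- sample(ncol(pairs), 190)
    shared <- idx[1:30]
    onlyA <- idx[31:100]    # 100-edge network: 30 shared + 70 own
    onlyB <- idx[101:190]   # 120-edge network: 30 shared + 90 own
    netA <- weightedNetwork(pairs[1, c(shared, onlyA)],
                            pairs[2, c(shared, onlyA)], runif(100, 0.1, 1))
    netB <- weightedNetwork(pairs[1, c(shared, onlyB)],
                            pairs[2, c(shared, onlyB)], runif(120, 0.1, 1))
    p <- buildUnion(list(netA, netB))
    expect_equal(numEdges(p), 190)
    expect_equal(sum(p@observed[, 1] & p@observed[, 2]), 30)
})

test_that("network integration equals the brute-force oracle on small fixtures", {
    set.seed(21)
    for (i in 1:20) {
        m <- sample(2:4, 1)
        nets <- lapply(seq_len(m), function(k)
            randomNetwork(sample(5:10, 1), density = 0.5,
                          seed = 1000 * i + k,
                          genes = sprintf("n%03d", 1:10)))
        inet <- integrateNetworks(nets)
        expected <- oracleIntegrateNetworks(nets, theta = 0.3)
        got <- edgeTable(inet)
        expect_equal(paste(got$from, got$to), names(expected))
        expect_equal(got$weight, unname(expected), tolerance = 1e-10)
    }
})

test_that("integration preserves equal inputs, order and union topology", {
    nets <- lapply(1:3, function(k) randomNetwork(8, density = 0.6, seed = 77))
    inet <- integrateNetworks(nets)
    # m identical networks reproduce the input wherever weights are interior
    w0 <- edgeTable(nets[[1]])$weight
    interior <- w0 >= 0.001 & w0 <= 0.999
    expect_equal(edgeTable(inet)$weight[interior], w0[interior],
                 tolerance = 1e-12)
    # permutation invariance
    netsP <- lapply(1:4, function(k) randomNetwork(8, density = 0.4, seed = k))
    i1 <- integrateNetworks(netsP)
    i2 <- integrateNetworks(netsP[c(3, 1, 4, 2)])
    expect_equal(edgeTable(i1), edgeTable(i2), tolerance = 1e-14)
    # output node/edge sets equal the union's exactly; weights strictly inside (0,1)
    p <- buildUnion(netsP)
    expect_identical(nodes(i1), nodes(p))
    expect_identical(edgeTable(i1)[, c("from", "to")], edgeTable(p))
    expect_true(all(edgeTable(i1)$weight > 0 & edgeTable(i1)$weight < 1))
})

test_that("integrated weights respect the per-edge convexity bound", {
    nets <- lapply(1:4, function(k) randomNetwork(12, density = 0.3, seed = 30 + k))
    p <- buildUnion(nets)
    w <- edgeTable(integrateNetworks(p))$weight
    lo <- apply(p@weights, 1, min)
    hi <- apply(p@weights, 1, max)
    expect_true(all(w >= lo - 1e-12 & w <= hi + 1e-12))
})
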