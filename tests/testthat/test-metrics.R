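triangle <- thresholdedGraph(rbind(c(1, 2), c(1, 3), c(2, 3)), nodes = 3,
                             mode = "binary")
star <- thresholdedGraph(cbind(1, 2:5), nodes = 5, mode = "binary")

test_that("clustering matches closed forms on canonical graphs", {
    cc <- clusteringCoefficient(triangle)
    expect_equal(unname(cc$node), c(1, 1, 1))
    expect_equal(cc$mean, 1)
    expect_equal(clusteringCoefficient(star)$mean, 0)
})

test_that("distances, path length and efficiencies match closed forms", {
    path3 <- thresholdedGraph(rbind(c(1, 2), c(2, 3)), nodes = 3,
                              mode = "binary")
    d <- shortestDistances(path3)
    expect_equal(d[1, 3], 2)
    # two components: cross distances are infinite
    twoComp <- thresholdedGraph(rbind(c(1, 2), c(3, 4)), nodes = 4,
                                mode = "binary")
    d2 <- shortestDistances(twoComp)
    expect_true(is.infinite(d2[1, 3]))
    # 4 nodes, one edge: sum of reciprocal distances is 2 -> Lp = 12/2 = 6
    oneEdge <- thresholdedGraph(rbind(c(1, 2)), nodes = 4, mode = "binary")
    expect_equal(characteristicPathLength(shortestDistances(oneEdge)), 6)
    expect_equal(characteristicPathLength(shortestDistances(triangle)), 1)
    # complete graph: everything is 1
    k4 <- thresholdedGraph(t(combn(4, 2)), nodes = 4, mode = "binary")
    d4 <- shortestDistances(k4)
    expect_equal(globalEfficiency(d4), 1)
    expect_equal(localEfficiency(k4), 1)
    expect_equal(localEfficiency(star), 0)
    # edgeless graph
    none <- thresholdedGraph(matrix(integer(0), ncol = 2), numeric(0),
                             nodes = 5)
    expect_equal(globalEfficiency(shortestDistances(none)), 0)
    expect_error(characteristicPathLength(shortestDistances(none)),
                 "no connected")
})

test_that("metrics agree with brute-force oracles and igraph on random graphs", {
    for (seed in 1:10) {
        weighted <- seed %% 2 == 0
        g <- randomTestGraph(n = 14, nEdges = 28, weighted = weighted,
                             seed = seed)
        A <- adjacencyMatrix(g)
        expect_equal(clusteringCoefficient(g)$mean,
                     oracleClustering(A, weighted)$mean, tolerance = 1e-12)
        d <- shortestDistances(g)
        dOracle <- oracleDistances(A)
        expect_equal(unname(d), unname(dOracle), tolerance = 1e-12)
        expect_equal(unname(d), unname(igraph::distances(
            asIgraph(g, distance = TRUE))), tolerance = 1e-12)
        expect_equal(characteristicPathLength(d), oracleLp(dOracle),
                     tolerance = 1e-12)
        expect_equal(globalEfficiency(d), oracleEglob(dOracle),
                     tolerance = 1e-12)
        expect_equal(localEfficiency(g), oracleEloc(A), tolerance = 1e-12)
        # harmonic-mean identity
        expect_equal(characteristicPathLength(d), 1 / globalEfficiency(d))
    }
})

test_that("metrics are invariant under node relabeling", {
    g <- randomTestGraph(n = 12, nEdges = 24, weighted = TRUE, seed = 7)
    set.seed(77)
    perm <- sample(12)
    e <- graphEdges(g)
    g2 <- thresholdedGraph(cbind(perm[e[, 1]], perm[e[, 2]]),
                           edgeWeights(g), nodes = 12)
    expect_equal(clusteringCoefficient(g2)$mean,
                 clusteringCoefficient(g)$mean, tolerance = 1e-12)
    expect_equal(globalEfficiency(shortestDistances(g2)),
                 globalEfficiency(shortestDistances(g)), tolerance = 1e-12)
    expect_equal(localEfficiency(g2), localEfficiency(g), tolerance = 1e-12)
})

test_that("the fast clustering curve equals the object pipeline", {
    r <- randomCorMatrix(40, seed = 18)
    net <- corNetwork(r)
    sched <- sparsitySchedule(0.09, 0.30, 0.03)
    for (mode in c("weighted", "binary")) {
        fast <- cbfnet:::.cpCurveFromCor(r, sched, mode, "absolute")
        slow <- vapply(sched, function(S)
            clusteringCoefficient(applySparsity(net, S, mode = mode))$mean,
            numeric(1))
        expect_equal(fast, slow, tolerance = 1e-12)
    }
})

test_that("random references preserve degrees, edges and weight multiset", {
    g <- randomTestGraph(n = 30, nEdges = 80, weighted = TRUE, seed = 19)
    refs <- randomReferences(g, n = 15, seed = 20)
    degOrig <- colSums(adjacencyMatrix(g) > 0)
    for (ref in refs) {
        expect_equal(colSums(adjacencyMatrix(ref) > 0), degOrig)
        expect_equal(nrow(graphEdges(ref)), 80)
        expect_equal(sort(edgeWeights(ref)), sort(edgeWeights(g)))
        expect_true(all(graphEdges(ref)[, 1] < graphEdges(ref)[, 2]))
    }
    # rewiring actually shuffles topology
    expect_false(identical(graphEdges(refs[[1]]), graphEdges(g)))
    # seeded determinism
    refs2 <- randomReferences(g, n = 15, seed = 20)
    expect_identical(lapply(refs, graphEdges), lapply(refs2, graphEdges))
    expect_error(randomReferences(thresholdedGraph(rbind(c(1, 2)),
                                                   nodes = 3)),
                 "at least 2 edges")
})

test_that("a ring lattice is far more clustered than its rewired references", {
    gammas <- vapply(1:5, function(seed) {
        g <- ringLattice(60, 6)
        refs <- randomReferences(g, n = 20, seed = seed)
        normalizedMetrics(g, refs)$gamma
    }, numeric(1))
    expect_true(all(gammas > 1.5))
})

test_that("normalization against identical references is exactly one", {
    g <- randomTestGraph(n = 15, nEdges = 40, weighted = TRUE, seed = 21)
    m <- normalizedMetrics(g, list(g, g, g))
    expect_equal(m$gamma, 1)
    expect_equal(m$lambda, 1)
    expect_equal(m$sigma, 1)
    # sigma = gamma / lambda bit-exactly
    g2 <- randomTestGraph(n = 15, nEdges = 40, weighted = TRUE, seed = 22)
    refs <- randomReferences(g2, n = 5, seed = 23)
    m2 <- normalizedMetrics(g2, refs)
    expect_identical(m2$sigma, m2$gamma / m2$lambda)
})

test_that("metric curves carry trapezoidal AUCs and handle single points", {
    ch <- generateCohort(smallSpec(seed = 24))
    net <- correlationNetwork(residualizeCBF(cohortGroup(ch, "A")))
    sched <- sparsitySchedule(0.15, 0.30, 0.05)
    crv <- metricCurve(net, sched, nRandom = 5, seed = 25)
    tab <- metricsTable(crv)
    expect_equal(nrow(tab), length(sched))
    auc <- aucValues(crv)
    manual <- sum(diff(sched) * (tab$Cp[-1] + tab$Cp[-nrow(tab)]) / 2)
    expect_equal(unname(auc["Cp"]), manual, tolerance = 1e-12)
    expect_equal(unname(auc["sigma"]),
                 sum(diff(sched) * (tab$sigma[-1] + tab$sigma[-4]) / 2),
                 tolerance = 1e-12)
    # single-point schedule reports the raw value with zero width
    one <- metricCurve(net, 0.2, nRandom = 5, seed = 26)
    expect_equal(unname(aucValues(one)["Eglob"]),
                 metricsTable(one)$Eglob[1])
    expect_equal(one@aucWidth, 0)
    # determinism
    crv2 <- metricCurve(net, sched, nRandom = 5, seed = 25)
    expect_identical(metricsTable(crv), metricsTable(crv2))
})

test_that("metric curves export tidy TSV and JSON summaries", {
    ch <- generateCohort(smallSpec(seed = 27))
    net <- correlationNetwork(residualizeCBF(cohortGroup(ch, "B")))
    crv <- metricCurve(net, sparsitySchedule(0.15, 0.25, 0.05),
                       nRandom = 4, seed = 28)
    pt <- tempfile(fileext = ".tsv")
    writeMetricsTSV(crv, pt, group = "B")
    tab <- read.delim(pt)
    expect_named(tab, c("group", "mode", "sparsity", "metric", "value"))
    expect_equal(nrow(tab), 7 * 3 + 7)       # per-sparsity rows + AUC rows
    expect_equal(tab$value[tab$metric == "Cp_auc"],
                 unname(aucValues(crv)["Cp"]), tolerance = 1e-12)
    pj <- tempfile(fileext = ".json")
    writeMetricsJSON(crv, pj, group = "B")
    js <- jsonlite::read_json(pj)
    expect_equal(js$auc$sigma, unname(aucValues(crv)["sigma"]))
    expect_equal(js$n_random, 4)
    expect_length(js$schedule, 3)
})
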