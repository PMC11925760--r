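test_that("residualization removes covariates exactly", {
    ch <- generateCohort(smallSpec(seed = 11))
    a <- cohortGroup(ch, "A")
    res <- residualizeCBF(a)
    expect_true(isResidualized(res))
    vals <- cbfMatrix(res)
    info <- subjectInfo(res)
    expect_lt(max(abs(colMeans(vals))), 1e-10)
    for (cov in c("age", "sex")) {
        cors <- abs(apply(vals, 2, function(y) cor(y, info[[cov]])))
        expect_lt(max(cors), 1e-10)
    }
    # values that are an exact linear function of age residualize to zero
    lin <- RegionalCBF(cbind(r1 = 3 - 0.2 * info$age,
                             r2 = 10 + info$age + 2 * info$sex),
                       info)
    expect_lt(max(abs(cbfMatrix(residualizeCBF(lin)))), 1e-10)
})

test_that("residualization reduces to mean-centering for orthogonal covariates", {
    # balanced sex, identical values in both sex groups, so the sex slope
    # is exactly zero and residuals reduce to mean-centered values
    subj <- data.frame(subject_id = sprintf("s%d", 1:8),
                       group = "A", age = 50,
                       sex = rep(c(0, 1), each = 4))
    y <- rep(c(1, 5, 2, 8), 2)
    m <- RegionalCBF(cbind(r1 = y), subj)
    res <- residualizeCBF(m, covariates = "sex")
    expect_equal(unname(cbfMatrix(res)[, 1]), y - mean(y), tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected by covariate name", {
    subj <- data.frame(subject_id = sprintf("s%d", 1:8), group = "A",
                       age = seq(40, 70, length.out = 8), sex = 1)
    m <- RegionalCBF(matrix(rnorm(16), 8, 2,
                            dimnames = list(NULL, c("r1", "r2"))), subj)
    expect_error(residualizeCBF(m), "sex")
})

test_that("the covariance network matches a pairwise Pearson loop oracle", {
    ch <- generateCohort(smallSpec(seed = 12))
    res <- residualizeCBF(cohortGroup(ch, "A"))
    net <- correlationNetwork(res)
    r <- corMatrix(net)
    vals <- cbfMatrix(res)
    pearson <- function(x, y) {
        xm <- x - mean(x); ym <- y - mean(y)
        sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
    }
    for (i in 1:5) for (j in (i + 1):6)
        expect_equal(r[i, j], pearson(vals[, i], vals[, j]),
                     tolerance = 1e-12)
    expect_equal(unname(diag(r)), rep(1, nrow(r)))
    expect_true(isSymmetric(r))
})

test_that("covariance network handles perfect correlation, degeneracy and invariance", {
    subj <- data.frame(subject_id = sprintf("s%d", 1:6), group = "A",
                       age = 50 + 1:6, sex = rep(0:1, 3))
    x <- c(1, 4, 2, 8, 5, 7)
    m <- RegionalCBF(cbind(a = x, b = 2 * x + 3, c = -x, d = rev(x)), subj)
    r <- corMatrix(correlationNetwork(m))
    expect_equal(r["a", "b"], 1)
    expect_equal(r["a", "c"], -1)
    # Pearson invariance to per-region affine rescaling
    m2 <- RegionalCBF(cbind(a = 10 * x - 4, b = 2 * x + 3, c = -x / 7,
                            d = rev(x) + 1), subj)
    expect_equal(corMatrix(correlationNetwork(m2)), r, tolerance = 1e-12)
    mConst <- RegionalCBF(cbind(a = x, b = rep(5, 6)), subj)
    expect_error(correlationNetwork(mConst), "constant region")
    expect_error(correlationNetwork(m[, 1:3]), "at least 4 subjects")
})

test_that("the sparsity schedule covers the documented grid", {
    s <- sparsitySchedule()
    expect_length(s, 22)
    expect_equal(s[1], 0.09)
    expect_equal(s[22], 0.30)
    expect_equal(diff(s), rep(0.01, 21))
    expect_equal(sparsitySchedule(0.1, 0.1, 0.01), 0.1)
    expect_equal(sparsitySchedule(0.05, 0.2, 0.05),
                 c(0.05, 0.10, 0.15, 0.20))
    expect_error(sparsitySchedule(0, 0.3), "min")
    expect_error(sparsitySchedule(0.3, 0.1), "min")
    expect_error(sparsitySchedule(0.1, 0.3, -0.01), "step")
})

test_that("sparsity thresholding keeps exactly the strongest edges", {
    r <- randomCorMatrix(20, seed = 13)
    net <- corNetwork(r)
    g <- applySparsity(net, 0.2)
    k <- round(0.2 * 20 * 19 / 2)
    expect_equal(nrow(graphEdges(g)), k)
    # brute-force sort-and-take oracle
    absr <- abs(r)
    vals <- sort(absr[upper.tri(absr)], decreasing = TRUE)[seq_len(k)]
    expect_equal(sort(edgeWeights(g), decreasing = TRUE), vals,
                 tolerance = 1e-12)
    # every kept edge is at least as strong as every dropped pair
    A <- adjacencyMatrix(g)
    dropped <- absr[upper.tri(absr)][absr[upper.tri(absr)] < min(vals)]
    expect_true(all(edgeWeights(g) >= max(dropped)))
    # S = 1 gives the complete graph
    expect_equal(nrow(graphEdges(applySparsity(net, 1))), 190)
    expect_error(applySparsity(net, 0.001), "empty graph")
})

test_that("thresholded edge sets are nested along the schedule", {
    r <- randomCorMatrix(30, seed = 14)
    net <- corNetwork(r)
    sched <- sparsitySchedule(0.09, 0.30, 0.03)
    prev <- NULL
    for (S in sched) {
        g <- applySparsity(net, S)
        keys <- paste(graphEdges(g)[, 1], graphEdges(g)[, 2])
        if (!is.null(prev)) expect_true(all(prev %in% keys))
        prev <- keys
    }
})

test_that("binary mode yields unit weights on the same edge set", {
    r <- randomCorMatrix(25, seed = 15)
    net <- corNetwork(r)
    gw <- applySparsity(net, 0.15, mode = "weighted")
    gb <- applySparsity(net, 0.15, mode = "binary")
    expect_identical(graphEdges(gw), graphEdges(gb))
    expect_true(all(edgeWeights(gb) == 1))
    expect_true(all(edgeWeights(gw) > 0 & edgeWeights(gw) <= 1))
})

test_that("the mean-degree criterion uses 2 ln N", {
    r <- randomCorMatrix(116, nSubj = 50, seed = 16)
    g <- applySparsity(corNetwork(r), 0.09)
    chk <- checkDegreeCriterion(g)
    expect_equal(chk$meanDegree, 2 * 600 / 116, tolerance = 1e-12)
    expect_equal(chk$threshold, 2 * log(116))
    expect_true(chk$pass)
    k116 <- applySparsity(corNetwork(r), 1)
    expect_equal(checkDegreeCriterion(k116)$meanDegree, 115)
    empty <- thresholdedGraph(matrix(integer(0), ncol = 2), numeric(0),
                              nodes = 10)
    chk0 <- checkDegreeCriterion(empty)
    expect_equal(chk0$meanDegree, 0)
    expect_false(chk0$pass)
})

test_that("network exports write well-formed TSV", {
    r <- randomCorMatrix(8, seed = 17)
    net <- corNetwork(r)
    p1 <- tempfile(fileext = ".tsv")
    writeNetworkTSV(net, p1)
    m <- as.matrix(read.delim(p1, row.names = 1))
    expect_equal(unname(m), unname(r), tolerance = 1e-12)
    g <- applySparsity(net, 0.3)
    p2 <- tempfile(fileext = ".tsv")
    writeEdgeListTSV(g, p2)
    el <- read.delim(p2)
    expect_equal(nrow(el), nrow(graphEdges(g)))
    expect_named(el, c("region_a", "region_b", "weight"))
})
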