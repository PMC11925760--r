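test_that("identical groups give zero difference and p = 1", {
    ch <- generateCohort(smallSpec(seed = 31))
    a <- cohortGroup(ch, "A")
    d <- realDifference(a, a, metric = "Cp")
    expect_identical(d, 0)
    pt <- permutationTest(a, a, metric = "Cp", nPerm = 30, seed = 32)
    # every permuted |diff| >= 0 = |real diff|, so the >= convention gives 1
    expect_equal(pValue(pt), 1)
})

test_that("the observed difference is antisymmetric in the group order", {
    ch <- generateCohort(smallSpec(seed = 33, rhoWithinA = 0.5))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    expect_equal(realDifference(a, b, metric = "Cp"),
                 -realDifference(b, a, metric = "Cp"), tolerance = 1e-15)
    # per-sparsity level returns one difference per threshold
    sched <- sparsitySchedule(0.1, 0.3, 0.05)
    v <- realDifference(a, b, metric = "Cp", level = "per-sparsity",
                        schedule = sched)
    expect_length(v, length(sched))
})

test_that("a dominant real difference yields p = 0 under the count formula", {
    ch <- generateCohort(cohortSpec(nGroupA = 12, nGroupB = 12,
                                    nRegions = 30, nModules = 3,
                                    rhoWithinA = 0.9, rhoWithinB = 0,
                                    rhoBetween = 0, noiseSd = 0.2,
                                    seed = 34))
    pt <- permutationTest(cohortGroup(ch, "A"), cohortGroup(ch, "B"),
                          metric = "Cp", nPerm = 40, seed = 35)
    expect_true(all(abs(nullDistribution(pt)) <
                    abs(observedDifference(pt))))
    expect_equal(pValue(pt), 0)
    # the plus-one variant can never be exactly zero
    pt1 <- permutationTest(cohortGroup(ch, "A"), cohortGroup(ch, "B"),
                           metric = "Cp", nPerm = 40, seed = 35,
                           pFormula = "plus-one")
    expect_equal(pValue(pt1), 1 / 41)
})

test_that("the identity permutation reproduces the real difference (p = 1)", {
    ch <- generateCohort(smallSpec(seed = 36))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    pool <- cbfnet:::.poolGroups(a, b, c("age", "sex"))
    res <- cbfnet:::.permTestCore(
        pool, metric = "Cp", level = "auc", mode = "weighted",
        schedule = sparsitySchedule(0.1, 0.3, 0.1), nRandom = 0,
        rank = "absolute", perms = list(seq_len(pool$nA + pool$nB)),
        refSeeds = c(1L, 2L), alternative = "two.sided",
        pFormula = "count", seed = 1L)
    expect_equal(nullDistribution(res)[1, ], observedDifference(res))
    expect_equal(pValue(res), 1)
})

test_that("permutation tests are deterministic given the seed", {
    ch <- generateCohort(smallSpec(seed = 37, rhoWithinA = 0.45))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    sched <- sparsitySchedule(0.1, 0.3, 0.05)
    p1 <- permutationTest(a, b, metric = "Cp", schedule = sched,
                          nPerm = 25, seed = 38)
    p2 <- permutationTest(a, b, metric = "Cp", schedule = sched,
                          nPerm = 25, seed = 38)
    expect_identical(nullDistribution(p1), nullDistribution(p2))
    expect_identical(pValue(p1), pValue(p2))
    p3 <- permutationTest(a, b, metric = "Cp", schedule = sched,
                          nPerm = 25, seed = 39)
    expect_false(identical(nullDistribution(p1), nullDistribution(p3)))
})

test_that("sidedness options count exceedances consistently", {
    ch <- generateCohort(smallSpec(seed = 40, rhoWithinA = 0.45))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    sched <- sparsitySchedule(0.1, 0.3, 0.1)
    args <- list(a, b, metric = "Cp", schedule = sched, nPerm = 40,
                 seed = 41)
    p2s <- do.call(permutationTest, c(args, alternative = "two.sided"))
    pgr <- do.call(permutationTest, c(args, alternative = "greater"))
    pls <- do.call(permutationTest, c(args, alternative = "less"))
    null <- nullDistribution(p2s)
    obs <- observedDifference(p2s)
    expect_equal(pValue(p2s), mean(abs(null) >= abs(obs)))
    expect_equal(pValue(pgr), mean(null >= obs))
    expect_equal(pValue(pls), mean(null <= obs))
})

test_that("compareAll reports every metric-mode pair from one stream", {
    ch <- generateCohort(smallSpec(seed = 42))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    sched <- sparsitySchedule(0.12, 0.24, 0.04)
    rep1 <- compareAll(a, b, metrics = c("Cp", "Eglob"),
                       modes = c("weighted", "binary"), schedule = sched,
                       nPerm = 15, seed = 43, nRandom = 3)
    expect_length(rep1$results, 4)
    expect_setequal(names(rep1$results),
                    c("Cp.weighted", "Eglob.weighted", "Cp.binary",
                      "Eglob.binary"))
    expect_true(all(rep1$summary$p >= 0 & rep1$summary$p <= 1))
    expect_equal(rep1$results$Cp.weighted@nGroupA, 12)
    expect_equal(rep1$results$Cp.weighted@nGroupB, 14)
    # deterministic rerun
    rep2 <- compareAll(a, b, metrics = c("Cp", "Eglob"),
                       modes = c("weighted", "binary"), schedule = sched,
                       nPerm = 15, seed = 43, nRandom = 3)
    expect_identical(rep1$summary, rep2$summary)
    # identical groups: all p-values are 1 under the >= convention
    repNull <- compareAll(a, a, metrics = "Cp", modes = "weighted",
                          schedule = sched, nPerm = 10, seed = 44)
    expect_true(all(repNull$summary$p == 1))
})

test_that("group sizes and region sets are validated", {
    ch <- generateCohort(smallSpec(seed = 45))
    a <- cohortGroup(ch, "A")
    b <- cohortGroup(ch, "B")
    expect_error(permutationTest(a[, 1:3], b, metric = "Cp"),
                 "at least 4 subjects")
    expect_error(permutationTest(a, b, metric = "Cp", nPerm = 0), "nPerm")
    expect_error(permutationTest(a[1:10, ], b, metric = "Cp"),
                 "different region sets")
})
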