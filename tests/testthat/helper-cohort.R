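# Shared cohort settings for tests.

# Small, fast cohort for unit tests.
smallSpec <- function(seed = 1, ...) {
    cohortSpec(nGroupA = 12, nGroupB = 14, nRegions = 24, nModules = 4,
               seed = seed, ...)
}

# Within-module correlation raise planted in group A for the power and
# concordance checks; calibrated during development so the true weighted
# Cp-AUC difference is about three permutation-null SDs (see the methods
# vignette).
plantedRhoWithinA <- 0.53

# Planted-effect simulation runs shared by the power and mode-concordance
# acceptance checks; computed once per test session.
.plantedCache <- new.env(parent = emptyenv())
plantedEffectRuns <- function(nDatasets = 100) {
    key <- as.character(nDatasets)
    if (!is.null(.plantedCache[[key]])) return(.plantedCache[[key]])
    runs <- t(vapply(seq_len(nDatasets), function(i) {
        ch <- generateCohort(cohortSpec(rhoWithinA = plantedRhoWithinA,
                                        seed = 100000 + i))
        a <- cohortGroup(ch, "A")
        b <- cohortGroup(ch, "B")
        pt <- permutationTest(a, b, metric = "Cp", nPerm = 200,
                              seed = 200000 + i, nRandom = 10)
        c(p = pValue(pt),
          dCpW = observedDifference(pt),
          dCpB = realDifference(a, b, metric = "Cp", mode = "binary"),
          dSigW = realDifference(a, b, metric = "sigma", nRandom = 10,
                                 seed = 300000 + i),
          dSigB = realDifference(a, b, metric = "sigma", mode = "binary",
                                 nRandom = 10, seed = 400000 + i))
    }, numeric(5)))
    .plantedCache[[key]] <- as.data.frame(runs)
    .plantedCache[[key]]
}
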