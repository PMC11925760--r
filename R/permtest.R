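.metricChoices <- c("Cp", "Lp", "gamma", "lambda", "sigma", "Eloc", "Eglob")

# Assemble pooled data for the permutation machinery.
.poolGroups <- function(dataA, dataB, covariates) {
    stopifnot(is(dataA, "RegionalCBF"), is(dataB, "RegionalCBF"))
    if (!identical(regionNames(dataA), regionNames(dataB)))
        .stopf("the two groups have different region sets")
    if (ncol(dataA) < 4L || ncol(dataB) < 4L)
        .stopf("need at least 4 subjects per group")
    infoA <- subjectInfo(dataA)
    infoB <- subjectInfo(dataB)
    miss <- setdiff(covariates, colnames(infoA))
    if (length(miss))
        .stopf("unknown covariate(s): %s", paste(miss, collapse = ", "))
    Y <- rbind(cbfMatrix(dataA), cbfMatrix(dataB))
    X <- cbind(1, as.matrix(rbind(infoA[, covariates, drop = FALSE],
                                  infoB[, covariates, drop = FALSE])))
    list(Y = Y, X = X, nA = ncol(dataA), nB = ncol(dataB))
}

#' Real (observed) group difference of a global network metric
#'
#' Builds each group's covariance network from scratch — residualize the
#' covariates within the group, correlate regions across its subjects,
#' threshold over the schedule, compute the metric — and returns the group A
#' minus group B difference, either per sparsity level or as the AUC over
#' the schedule.
#'
#' @param dataA,dataB [RegionalCBF-class] objects with identical regions.
#' @param metric one of `"Cp", "Lp", "gamma", "lambda", "sigma", "Eloc",
#'   "Eglob"`.
#' @param level `"auc"` (scalar) or `"per-sparsity"` (vector).
#' @param mode `"weighted"` or `"binary"`.
#' @param schedule sparsity schedule.
#' @param nRandom random references per threshold (normalized metrics only).
#' @param seed RNG seed for the references.
#' @param covariates covariates regressed out within each group.
#' @param rank edge ranking (see [applySparsity()]).
#' @return numeric difference (A - B).
#' @export
realDifference <- function(dataA, dataB, metric = "Cp",
                           level = c("auc", "per-sparsity"),
                           mode = c("weighted", "binary"),
                           schedule = sparsitySchedule(), nRandom = 100,
                           seed = 1L, covariates = c("age", "sex"),
                           rank = c("absolute", "positive")) {
    level <- match.arg(level)
    mode <- match.arg(mode)
    rank <- match.arg(rank)
    metric <- match.arg(metric, .metricChoices)
    p <- .poolGroups(dataA, dataB, covariates)
    seeds <- .deriveSeeds(seed, 2L)
    a <- .groupStat(p$Y, p$X, seq_len(p$nA), schedule, metric, mode, rank,
                    level, nRandom, seeds[1])
    b <- .groupStat(p$Y, p$X, p$nA + seq_len(p$nB), schedule, metric, mode,
                    rank, level, nRandom, seeds[2])
    a - b
}

# Core permutation engine; perms is a list of pooled-index permutations so
# that several metrics can share one permutation stream.
.permTestCore <- function(pool, metric, level, mode, schedule, nRandom,
                          rank, perms, refSeeds, alternative, pFormula,
                          seed) {
    nA <- pool$nA
    nB <- pool$nB
    nTot <- nA + nB
    stat <- function(idxA, idxB, s) {
        stopifnot(length(idxA) == nA, length(idxB) == nB)  # sizes conserved
        sAB <- .deriveSeeds(s, 2L)
        a <- .groupStat(pool$Y, pool$X, idxA, schedule, metric, mode, rank,
                        level, nRandom, sAB[1])
        b <- .groupStat(pool$Y, pool$X, idxB, schedule, metric, mode, rank,
                        level, nRandom, sAB[2])
        a - b
    }
    observed <- stat(seq_len(nA), nA + seq_len(nB), refSeeds[1])
    nullMat <- matrix(NA_real_, nrow = length(perms),
                      ncol = length(observed))
    for (k in seq_along(perms)) {
        prm <- perms[[k]]
        nullMat[k, ] <- stat(prm[seq_len(nA)], prm[nA + seq_len(nB)],
                             refSeeds[k + 1L])
    }
    count <- switch(alternative,
        two.sided = colSums(abs(nullMat) >= rep(abs(observed),
                                                each = nrow(nullMat))),
        greater = colSums(nullMat >= rep(observed, each = nrow(nullMat))),
        less = colSums(nullMat <= rep(observed, each = nrow(nullMat))))
    pv <- if (pFormula == "count") count / length(perms)
          else (count + 1) / (length(perms) + 1)
    new("PermutationResult", metric = metric, mode = mode, level = level,
        sparsity = if (level == "per-sparsity") schedule else NA_real_,
        observed = as.numeric(observed), null = nullMat,
        pValue = as.numeric(pv), nPerm = length(perms),
        seed = as.integer(seed), nGroupA = as.integer(nA),
        nGroupB = as.integer(nB),
        settings = list(schedule = schedule, nRandom = nRandom, rank = rank,
                        alternative = alternative, pFormula = pFormula))
}

#' Group-relabeling permutation test on a global network metric
#'
#' The observed difference is compared against a null distribution obtained
#' by pooling all subjects, randomly reassigning them to two groups of the
#' original sizes, and rerunning the entire network construction
#' (residualization, correlation, thresholding, metric — and, for normalized
#' metrics, fresh random references seeded per permutation). The p-value is
#' the fraction of permutations whose difference magnitude reaches the
#' observed one (ties count as exceedances); `pFormula = "plus-one"` gives
#' the (count + 1) / (nPerm + 1) variant.
#'
#' @inheritParams realDifference
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed driving permutations and references.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   for the A - B difference.
#' @param pFormula `"count"` (occurrences / nPerm) or `"plus-one"`.
#' @return a [PermutationResult-class].
#' @export
permutationTest <- function(dataA, dataB, metric = "Cp",
                            level = c("auc", "per-sparsity"),
                            mode = c("weighted", "binary"),
                            schedule = sparsitySchedule(), nPerm = 1000,
                            seed = 1L, nRandom = 100,
                            covariates = c("age", "sex"),
                            rank = c("absolute", "positive"),
                            alternative = c("two.sided", "greater", "less"),
                            pFormula = c("count", "plus-one")) {
    level <- match.arg(level)
    mode <- match.arg(mode)
    rank <- match.arg(rank)
    alternative <- match.arg(alternative)
    pFormula <- match.arg(pFormula)
    metric <- match.arg(metric, .metricChoices)
    if (nPerm < 1L) .stopf("nPerm must be at least 1")
    pool <- .poolGroups(dataA, dataB, covariates)
    nTot <- pool$nA + pool$nB
    rng <- .withSeed(seed, list(
        perms = lapply(seq_len(nPerm), function(i) sample.int(nTot)),
        refSeeds = sample.int(.Machine$integer.max - 1L, nPerm + 1L)))
    .permTestCore(pool, metric, level, mode, schedule, nRandom, rank,
                  rng$perms, rng$refSeeds, alternative, pFormula, seed)
}

#' @describeIn PermutationResult observed A - B difference.
#' @export
setMethod("observedDifference", "PermutationResult", function(x) x@observed)

#' @describeIn PermutationResult matrix of permuted differences
#'   (`nPerm` rows).
#' @export
setMethod("nullDistribution", "PermutationResult", function(x) x@null)

#' @describeIn PermutationResult permutation p-value(s).
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf("PermutationResult: %s (%s, %s), groups %d vs %d\n",
                object@metric, object@mode, object@level,
                object@nGroupA, object@nGroupB))
    if (object@level == "auc")
        cat(sprintf("  observed diff = %.5g, p = %.4g (%d permutations)\n",
                    object@observed, object@pValue, object@nPerm))
    else
        cat(sprintf("  per-sparsity: min p = %.4g at S = %.2f (%d permutations)\n",
                    min(object@pValue),
                    object@sparsity[which.min(object@pValue)], object@nPerm))
})

#' Permutation tests for several metrics and both network modes
#'
#' Runs [permutationTest()] for every metric in `metrics` and every mode in
#' `modes`. Within a mode, all metrics share one permutation stream (the
#' identical relabelings), so cross-metric comparisons are not confounded by
#' Monte-Carlo variation in the relabeling.
#'
#' @inheritParams permutationTest
#' @param metrics character vector of metric names.
#' @param modes subset of `c("weighted", "binary")`.
#' @return list with `results` (list of [PermutationResult-class], named
#'   `<metric>.<mode>`) and `summary` (data.frame of observed differences
#'   and p-values).
#' @export
compareAll <- function(dataA, dataB, metrics = .metricChoices,
                       modes = c("weighted", "binary"),
                       level = c("auc", "per-sparsity"),
                       schedule = sparsitySchedule(), nPerm = 1000,
                       seed = 1L, nRandom = 100,
                       covariates = c("age", "sex"),
                       rank = c("absolute", "positive"),
                       alternative = c("two.sided", "greater", "less"),
                       pFormula = c("count", "plus-one")) {
    level <- match.arg(level)
    rank <- match.arg(rank)
    alternative <- match.arg(alternative)
    pFormula <- match.arg(pFormula)
    metrics <- match.arg(metrics, .metricChoices, several.ok = TRUE)
    modes <- match.arg(modes, c("weighted", "binary"), several.ok = TRUE)
    pool <- .poolGroups(dataA, dataB, covariates)
    nTot <- pool$nA + pool$nB
    modeSeeds <- .deriveSeeds(seed, length(modes))
    results <- list()
    for (mi in seq_along(modes)) {
        rng <- .withSeed(modeSeeds[mi], list(
            perms = lapply(seq_len(nPerm), function(i) sample.int(nTot)),
            refSeeds = sample.int(.Machine$integer.max - 1L, nPerm + 1L)))
        for (metric in metrics) {
            res <- .permTestCore(pool, metric, level, modes[mi], schedule,
                                 nRandom, rank, rng$perms, rng$refSeeds,
                                 alternative, pFormula, modeSeeds[mi])
            results[[paste(metric, modes[mi], sep = ".")]] <- res
        }
    }
    summary <- do.call(rbind, lapply(results, function(r)
        data.frame(metric = r@metric, mode = r@mode, level = r@level,
                   observed = if (r@level == "auc") r@observed else NA,
                   p = if (r@level == "auc") r@pValue else min(r@pValue))))
    rownames(summary) <- NULL
    list(results = results, summary = summary)
}
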